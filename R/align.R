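#' @include AllClasses.R
NULL

.blosum62 <- function() {
  if (is.null(.targasm$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .targasm$blosum62 <- e$BLOSUM62
  }
  .targasm$blosum62
}

#' Protein scoring scheme
#'
#' BLOSUM62 with affine gap penalties open 11 / extend 1 is the single
#' default (the conventional operating point of translated homology
#' search); a gap of length k costs `gapOpen + k * gapExtend`.
#'
#' @param matrix symmetric integer substitution matrix with amino-acid
#'   letter dimnames (default: BLOSUM62 as shipped with Biostrings).
#' @param gapOpen,gapExtend non-negative integer penalties.
#' @return a [ScoringScheme-class].
#' @export
scoringScheme <- function(matrix = NULL, gapOpen = 11L, gapExtend = 1L) {
  if (is.null(matrix)) matrix <- .blosum62()
  new("ScoringScheme", matrix = matrix, gapOpen = as.integer(gapOpen),
      gapExtend = as.integer(gapExtend))
}

#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman. Identity is matches over aligned columns;
#' `qCov` is the aligned span of `a` over its length. Equal-scoring
#' alignments are resolved deterministically (smallest end coordinates,
#' substitutions preferred over gaps in the traceback).
#'
#' @param a,b protein sequences (character or AAString); `a` is the query
#'   for coverage purposes.
#' @param scheme a [ScoringScheme-class].
#' @return a [LocalAlignment-class].
#' @examples
#' smithWaterman("MKT", "MKT")
#' @export
smithWaterman <- function(a, b, scheme = scoringScheme()) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in alignment")
  r <- cpp_smith_waterman(a, b, scheme@matrix, scheme@gapOpen,
                          scheme@gapExtend)
  new("LocalAlignment",
      score = as.integer(r$score),
      qStart = as.integer(r$q_start), qEnd = as.integer(r$q_end),
      tStart = as.integer(r$t_start), tEnd = as.integer(r$t_end),
      identity = if (r$columns > 0) r$matches / r$columns else 0,
      qCov = (r$q_end - r$q_start) / nchar(a),
      matches = as.integer(r$matches), columns = as.integer(r$columns))
}

# identity over the shorter sequence, the pruning measure of
# buildQuerySet(): matched columns / min(length)
.global_identity <- function(a, b, scheme) {
  r <- cpp_smith_waterman(a, b, scheme@matrix, scheme@gapOpen,
                          scheme@gapExtend)
  r$matches / min(nchar(a), nchar(b))
}
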