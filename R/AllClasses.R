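#' @include targasm-package.R
NULL

#' NucReads: a set of nucleotide reads with optional qualities
#'
#' The unit flowing through trimming, filtering, recruitment and assembly.
#' Qualities are stored as Phred+33 strings (the only supported FASTQ
#' encoding); mate information is stripped from read ids at parse time and
#' kept in the `mate` slot, so mate pairing is by bare id.
#'
#' @slot id character, unique-ish read identifiers (mate suffix removed).
#' @slot seq character over A,C,G,T,N.
#' @slot qual character, Phred+33 encoded, `NA` when absent.
#' @slot mate integer, 1, 2 or `NA`.
#' @export
setClass("NucReads", representation(
  id = "character", seq = "character", qual = "character",
  mate = "integer"))

setValidity("NucReads", function(object) {
  n <- length(object@id)
  if (length(object@seq) != n || length(object@qual) != n ||
      length(object@mate) != n)
    return("id, seq, qual and mate must have equal length")
  if (n == 0) return(TRUE)
  if (any(!nzchar(object@id))) return("empty read id")
  if (any(!nzchar(object@seq))) return("empty read sequence")
  if (any(grepl("[^ACGTNacgtn]", object@seq)))
    return("sequence letters outside {A,C,G,T,N}")
  has_q <- !is.na(object@qual)
  if (any(nchar(object@qual[has_q]) != nchar(object@seq[has_q])))
    return("quality string length differs from sequence length")
  if (any(!is.na(object@mate) & !(object@mate %in% c(1L, 2L))))
    return("mate flag must be 1, 2 or NA")
  TRUE
})

#' Construct a NucReads object
#'
#' @param id,seq,qual,mate parallel vectors; `qual` as Phred+33 strings or
#'   a list of integer Phred scores; `qual`/`mate` may be `NA`.
#' @return A [NucReads-class] object.
#' @export
NucReads <- function(id, seq, qual = NA_character_, mate = NA_integer_) {
  n <- length(id)
  if (is.list(qual))
    qual <- vapply(qual, function(q) {
      if (length(q) == 1 && is.na(q)) NA_character_
      else intToUtf8(as.integer(q) + 33L)
    }, character(1))
  qual <- rep_len(as.character(qual), n)
  mate <- rep_len(as.integer(mate), n)
  new("NucReads", id = as.character(id), seq = toupper(as.character(seq)),
      qual = qual, mate = mate)
}

#' @describeIn NucReads number of reads
#' @param x a NucReads object
#' @export
setMethod("length", "NucReads", function(x) length(x@id))

#' @export
setMethod("[", "NucReads", function(x, i, j, ..., drop = TRUE) {
  new("NucReads", id = x@id[i], seq = x@seq[i], qual = x@qual[i],
      mate = x@mate[i])
})

#' @export
setMethod("c", "NucReads", function(x, ...) {
  xs <- c(list(x), list(...))
  new("NucReads",
      id = unlist(lapply(xs, slot, "id")),
      seq = unlist(lapply(xs, slot, "seq")),
      qual = unlist(lapply(xs, slot, "qual")),
      mate = unlist(lapply(xs, slot, "mate")))
})

setMethod("show", "NucReads", function(object) {
  cat("NucReads of length", length(object), "\n")
  if (length(object)) {
    i <- seq_len(min(3L, length(object)))
    cat(paste0("  ", object@id[i], " (", nchar(object@seq[i]), " nt",
               ifelse(is.na(object@qual[i]), ", no qual", ""), ")\n"),
        sep = "")
    if (length(object) > 3) cat("  ...\n")
  }
})

#' Accessors for NucReads
#'
#' `readIds`, `readSeqs`, `readQuals` (Phred+33 strings), `qualInts`
#' (list of integer Phred scores) and `readMates`.
#' @param x a [NucReads-class] object
#' @return the corresponding vector (or list for `qualInts`).
#' @export
readIds <- function(x) x@id
#' @rdname readIds
#' @export
readSeqs <- function(x) setNames(x@seq, x@id)
#' @rdname readIds
#' @export
readQuals <- function(x) x@qual
#' @rdname readIds
#' @export
readMates <- function(x) x@mate
#' @rdname readIds
#' @export
qualInts <- function(x) {
  lapply(x@qual, function(q) {
    if (is.na(q)) NULL else utf8ToInt(q) - 33L
  })
}

#' GeneticCode: an NCBI codon translation table
#'
#' @slot tableId NCBI translation-table number.
#' @slot codonToAa named character of all 64 codons to amino-acid letters
#'   (`*` for stops).
#' @slot startCodons codons accepted as initiators (translated as M at ORF
#'   starts).
#' @export
setClass("GeneticCode", representation(
  tableId = "integer", codonToAa = "character", startCodons = "character"))

setValidity("GeneticCode", function(object) {
  if (length(object@codonToAa) != 64) return("codonToAa must have 64 entries")
  if (is.null(names(object@codonToAa))) return("codonToAa must be named")
  aa <- object@codonToAa[object@startCodons]
  if (any(is.na(aa))) return("start codon not among the 64 codons")
  if (any(aa == "*")) return("start codon translating to a stop")
  TRUE
})

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode table", object@tableId, "- stops:",
      paste(names(object@codonToAa)[object@codonToAa == "*"], collapse = ","),
      "- starts:", paste(object@startCodons, collapse = ","), "\n")
})

#' ScoringScheme: protein substitution matrix plus affine gap penalties
#'
#' @slot matrix symmetric integer substitution matrix (BLOSUM62 by default).
#' @slot gapOpen,gapExtend non-negative gap penalties; a gap of length k
#'   costs `gapOpen + k * gapExtend`.
#' @export
setClass("ScoringScheme", representation(
  matrix = "matrix", gapOpen = "integer", gapExtend = "integer"))

setValidity("ScoringScheme", function(object) {
  m <- object@matrix
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    return("substitution matrix must be symmetric")
  if (median(diag(m)) < median(m[upper.tri(m)]))
    return("matrix diagonal must dominate off-diagonal scores")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    return("gap penalties must be >= 0")
  TRUE
})

#' LocalAlignment: result of a protein local alignment
#'
#' Coordinates are 0-based half-open on query (`q`) and target (`t`).
#' `identity` is matches over aligned columns; `qCov` the aligned query
#' span over the query length.
#' @export
setClass("LocalAlignment", representation(
  score = "integer", qStart = "integer", qEnd = "integer",
  tStart = "integer", tEnd = "integer", identity = "numeric",
  qCov = "numeric", matches = "integer", columns = "integer"))

setValidity("LocalAlignment", function(object) {
  if (object@qStart > object@qEnd || object@tStart > object@tEnd)
    return("inverted alignment coordinates")
  if ((object@score == 0) != (object@columns == 0))
    return("score is 0 iff the alignment is empty")
  if (object@identity < 0 || object@identity > 1 ||
      object@qCov < 0 || object@qCov > 1)
    return("identity and qCov must lie in [0,1]")
  TRUE
})

setMethod("show", "LocalAlignment", function(object) {
  cat(sprintf(
    "LocalAlignment score %d  q[%d,%d) t[%d,%d)  identity %.3f  qcov %.3f\n",
    object@score, object@qStart, object@qEnd, object@tStart, object@tEnd,
    object@identity, object@qCov))
})

#' @rdname LocalAlignment-class
#' @param x a LocalAlignment
#' @export
alignmentScore <- function(x) x@score

#' KmerIndex: canonical k-mer sets keyed by reference label
#'
#' Built by [buildKmerIndex()]; powers read classification and binning.
#' @slot k odd word size.
#' @slot labels reference labels.
#' @slot kmerSets named list of canonical k-mer character vectors.
#' @export
setClass("KmerIndex", representation(
  k = "integer", labels = "character", kmerSets = "list"))

setValidity("KmerIndex", function(object) {
  if (object@k %% 2L == 0L) return("k must be odd")
  if (anyDuplicated(object@labels)) return("duplicate reference labels")
  if (!identical(names(object@kmerSets), object@labels))
    return("kmerSets must be named by labels")
  TRUE
})

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex k =", object@k, "\n")
  for (l in object@labels)
    cat("  ", l, ": ", length(object@kmerSets[[l]]), " k-mers\n", sep = "")
})

#' SearchStrategy: one named gene-family search definition
#'
#' Bundles query sources, pruning limits, transcript match thresholds and
#' ORF parameters. Usually parsed from an INI file with
#' [readSearchStrategies()].
#' @export
setClass("SearchStrategy", representation(
  name = "character", queryFastaPaths = "character",
  minQueryLen = "integer", maxQueryLen = "integer",
  dedupIdentity = "numeric", matchMinScore = "integer",
  matchMinIdentity = "numeric", matchMinQcov = "numeric",
  orfMinLen = "integer", orfMaxLen = "integer",
  startCodons = "character", allowPartialOrfs = "logical"))

setValidity("SearchStrategy", function(object) {
  if (!nzchar(object@name)) return("strategy name must be non-empty")
  if (object@minQueryLen > object@maxQueryLen)
    return("min_query_len > max_query_len")
  if (object@orfMinLen > object@orfMaxLen)
    return("orf_min_len > orf_max_len")
  fr <- c(object@dedupIdentity, object@matchMinIdentity, object@matchMinQcov)
  if (any(fr <= 0 | fr > 1)) return("identity/coverage fractions must be in (0,1]")
  if (any(nchar(object@startCodons) != 3L))
    return("start codons must be 3-letter")
  TRUE
})

setMethod("show", "SearchStrategy", function(object) {
  cat("SearchStrategy '", object@name, "': ",
      length(object@queryFastaPaths), " query file(s), query length [",
      object@minQueryLen, ",", object@maxQueryLen, "] aa, dedup ",
      object@dedupIdentity, "\n", sep = "")
})

#' RecruitedReads: the targeted read subset for one search strategy
#'
#' @slot reads1 first mates (or single-end reads) as [NucReads-class].
#' @slot reads2 second mates, or `NULL` for single-end data.
#' @slot provenance named character, per-id recruitment stage
#'   (`"seed"` or `"enrich"`).
#' @export
setClass("RecruitedReads", representation(
  reads1 = "NucReads", reads2 = "ANY", provenance = "character"))

setValidity("RecruitedReads", function(object) {
  ids <- readIds(object@reads1)
  if (anyDuplicated(ids)) return("duplicate read ids in recruited set")
  if (!is.null(object@reads2)) {
    if (!is(object@reads2, "NucReads")) return("reads2 must be NucReads or NULL")
    if (!identical(readIds(object@reads2), ids))
      return("mate ids differ between reads1 and reads2")
  }
  if (!identical(sort(names(object@provenance)), sort(ids)))
    return("provenance must be named by the recruited ids")
  if (!all(object@provenance %in% c("seed", "enrich")))
    return("provenance values must be 'seed' or 'enrich'")
  TRUE
})

setMethod("show", "RecruitedReads", function(object) {
  cat("RecruitedReads:", length(object@reads1),
      if (is.null(object@reads2)) "single-end reads" else "pairs",
      sprintf("(%d seed, %d enrich)\n",
              sum(object@provenance == "seed"),
              sum(object@provenance == "enrich")))
})

#' @rdname RecruitedReads-class
#' @param x a RecruitedReads object
#' @export
provenance <- function(x) x@provenance

#' @rdname RecruitedReads-class
#' @export
recruitedIds <- function(x) readIds(x@reads1)

#' DeBruijnGraph: canonical k-mer graph for targeted assembly
#'
#' Nodes are canonical k-mers that survived the count filter; edges are
#' implicit k-1 overlaps with consistent orientation.
#' @slot k odd k-mer size.
#' @slot kmers canonical k-mer strings.
#' @slot counts occurrence counts parallel to `kmers`.
#' @export
setClass("DeBruijnGraph", representation(
  k = "integer", kmers = "character", counts = "numeric"))

setValidity("DeBruijnGraph", function(object) {
  if (length(object@kmers) != length(object@counts))
    return("kmers and counts must be parallel")
  TRUE
})

setMethod("show", "DeBruijnGraph", function(object) {
  cat("DeBruijnGraph k =", object@k, "with", length(object@kmers),
      "nodes\n")
})

#' @rdname DeBruijnGraph-class
#' @param x a DeBruijnGraph
#' @export
graphNodes <- function(x) setNames(x@counts, x@kmers)
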