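#' @include AllClasses.R
NULL

.load_codes <- function() {
  if (!is.null(.targasm$codes)) return(.targasm$codes)
  path <- system.file("extdata", "genetic_codes.tsv", package = "targasm",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "character",
                                   "integer"))
  codes <- lapply(split(tab, tab$table_id), function(d) {
    new("GeneticCode", tableId = d$table_id[1],
        codonToAa = setNames(d$aa, d$codon),
        startCodons = d$codon[d$start == 1L])
  })
  .targasm$codes <- codes
  codes
}

#' NCBI genetic-code tables
#'
#' Translation tables are shipped as a plain-text data file
#' (`extdata/genetic_codes.tsv`) keyed by NCBI table id; tables 1
#' (standard), 2 (vertebrate mitochondrial), 4, 5, 9 and 11
#' (bacterial/plastid) are embedded.
#'
#' @param tableId NCBI translation-table number.
#' @return `geneticCode` returns a [GeneticCode-class]; `geneticCodeIds`
#'   the available table numbers.
#' @examples
#' geneticCode(11)
#' @export
geneticCode <- function(tableId = 1L) {
  codes <- .load_codes()
  key <- as.character(as.integer(tableId))
  if (is.null(codes[[key]]))
    stop("unknown genetic-code table id: ", tableId,
         " (available: ", paste(names(codes), collapse = ", "), ")")
  codes[[key]]
}

#' @rdname geneticCode
#' @export
geneticCodeIds <- function() as.integer(names(.load_codes()))

#' Reverse complement of nucleotide sequences
#'
#' Vectorized; `N` is self-complementary, any other letter is an error.
#' @param seq character vector over A,C,G,T,N (case preserved).
#' @return character vector of reverse complements.
#' @examples
#' revComp(c("AAC", "ANT"))
#' @export
revComp <- function(seq) {
  out <- cpp_revcomp(as.character(seq))
  names(out) <- names(seq)
  out
}

#' Translate a nucleotide sequence in a given frame
#'
#' The trailing partial codon is dropped; codons containing N translate to
#' X; stops appear as `*` (internal stops allowed).
#'
#' @param seq nucleotide string(s).
#' @param code a [GeneticCode-class] (default: standard table 1).
#' @param frame 0, 1 or 2.
#' @return amino-acid string(s), length `floor((nchar(seq) - frame) / 3)`.
#' @examples
#' translateSeq("ATGAAATAG")
#' translateSeq("AGA", geneticCode(2))
#' @export
translateSeq <- function(seq, code = geneticCode(1L), frame = 0L) {
  stopifnot(is(code, "GeneticCode"), frame %in% 0:2)
  seq <- toupper(as.character(seq))
  if (any(!nzchar(seq))) stop("cannot translate an empty sequence")
  if (any(grepl("[^ACGTN]", seq)))
    stop("sequence letters outside {A,C,G,T,N}")
  map <- code@codonToAa
  vapply(seq, function(s) {
    n <- nchar(s)
    ncod <- (n - frame) %/% 3L
    if (ncod <= 0) return("")
    st <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    aa <- unname(map[substring(s, st, st + 2L)])
    aa[is.na(aa)] <- "X"  # codons containing N
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Six-frame translation
#'
#' Frames 0-2 on the forward strand followed by frames 0-2 on the reverse
#' complement, in that fixed order.
#' @inheritParams translateSeq
#' @return data.frame with columns `strand` (+/-), `frame` (0-2), `aa`.
#' @export
sixFrame <- function(seq, code = geneticCode(1L)) {
  stopifnot(length(seq) == 1, nchar(seq) >= 3)
  rc <- revComp(seq)
  data.frame(
    strand = rep(c("+", "-"), each = 3L),
    frame = rep(0:2, 2L),
    aa = c(vapply(0:2, function(f) translateSeq(seq, code, f), character(1)),
           vapply(0:2, function(f) translateSeq(rc, code, f), character(1))),
    stringsAsFactors = FALSE)
}

.codon_vectors <- function(code) {
  list(codons = names(code@codonToAa), aas = unname(code@codonToAa))
}
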