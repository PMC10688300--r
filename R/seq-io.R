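#' @include AllClasses.R
NULL

# A FASTA file must open with a header line; Biostrings tolerates some
# malformed inputs, so the first record boundary is checked explicitly to
# fail with a line number.
.check_fasta_header <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lineno <- 0L
  repeat {
    l <- readLines(con, n = 1L)
    if (length(l) == 0) stop("empty FASTA file: ", path)
    lineno <- lineno + 1L
    if (nzchar(trimws(l))) {
      if (!startsWith(l, ">"))
        stop("malformed FASTA (", path, " line ", lineno,
             "): sequence line before any header")
      return(invisible(TRUE))
    }
  }
}

.split_header <- function(x) {
  id <- sub("[ \t].*$", "", x)
  desc <- ifelse(grepl("[ \t]", x), sub("^[^ \t]+[ \t]+", "", x), "")
  list(id = id, desc = desc)
}

#' Read a FASTA file
#'
#' Plain or gzip-compressed. Multi-line records are concatenated; the part
#' of the header after the first whitespace is kept in
#' `mcols(x)$description`.
#'
#' @param path file path.
#' @param type "DNA" or "AA".
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] named
#'   by record id, in file order.
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  .check_fasta_header(path)
  x <- if (type == "DNA") readDNAStringSet(path) else readAAStringSet(path)
  h <- .split_header(names(x))
  names(x) <- h$id
  mcols(x)$description <- h$desc
  x
}

# Strip "/1", "/2" or Casava-style " 1:...:..." mate tails from a FASTQ id.
.strip_mate <- function(header) {
  mate <- rep(NA_integer_, length(header))
  tok <- sub("[ \t].*$", "", header)
  tail <- ifelse(grepl("[ \t]", header), sub("^[^ \t]+[ \t]+", "", header), "")
  m_space <- ifelse(grepl("^1:", tail), 1L, ifelse(grepl("^2:", tail), 2L, NA))
  m_slash <- ifelse(grepl("/1$", tok), 1L, ifelse(grepl("/2$", tok), 2L, NA))
  mate <- ifelse(!is.na(m_slash), m_slash, m_space)
  id <- sub("/[12]$", "", tok)
  list(id = id, mate = as.integer(mate))
}

#' Read and write FASTQ files
#'
#' Four-line records, Phred+33 qualities, transparent gzip (by ".gz"
#' suffix on write). Mate suffixes ("/1", "/2", or a space-delimited
#' "1:..."/"2:..." tail) are stripped from ids and recorded in the mate
#' slot. `writeFastq` followed by `readFastq` reproduces the records
#' exactly.
#'
#' @param path FASTQ file path.
#' @return `readFastq` returns a [NucReads-class] object.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  .validate_fastq(path)
  x <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  seqs <- as.character(x)
  quals <- as.character(mcols(x)$qualities)
  h <- .strip_mate(names(x))
  NucReads(id = h$id, seq = unname(seqs), qual = unname(quals),
           mate = h$mate)
}

# Structural check of the 4-line record layout; the backing parser is
# lenient about truncated records and length mismatches, which must be
# hard errors naming the record.
.validate_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  rec <- 0L
  repeat {
    block <- readLines(con, n = 4L)
    if (length(block) == 0) break
    rec <- rec + 1L
    if (length(block) < 4L)
      stop("malformed FASTQ (", path, "): record ", rec, " is truncated")
    if (!startsWith(block[1], "@") || !startsWith(block[3], "+"))
      stop("malformed FASTQ (", path, "): record ", rec,
           " lacks the @/+ record structure")
    if (nchar(block[2]) != nchar(block[4]))
      stop("malformed FASTQ (", path, "): record ", rec,
           " has sequence and quality of different lengths")
    if (any(utf8ToInt(block[4]) < 33))
      stop("malformed FASTQ (", path, "): record ", rec,
           " has quality characters below Phred+33")
  }
  invisible(TRUE)
}

#' @rdname readFastq
#' @param reads a [NucReads-class] object with qualities.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(is(reads, "NucReads"))
  if (any(is.na(reads@qual)))
    stop("cannot write FASTQ for reads without qualities")
  x <- QualityScaledDNAStringSet(DNAStringSet(setNames(reads@seq, reads@id)),
                                 PhredQuality(BStringSet(reads@qual)))
  writeQualityScaledXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs an XStringSet or named character vector.
#' @param path output path (".gz" for compressed).
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- BStringSet(seqs)
  writeXStringSet(seqs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}
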