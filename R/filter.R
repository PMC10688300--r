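#' @include AllClasses.R seq-io.R
NULL

#' Classification parameters
#'
#' @param minFrac minimum fraction of a read's (or pair's) k-mer positions
#'   that must hit the winning reference label; below it the read is
#'   unclassified. The default 0.25 is deliberately permissive: the
#'   classifier is a read sieve, not a taxonomic caller.
#' @export
classifyParams <- function(minFrac = 0.25) {
  stopifnot(minFrac > 0, minFrac <= 1)
  structure(list(minFrac = as.numeric(minFrac)), class = "ClassifyParams")
}

#' Build a canonical k-mer index over reference sequence sets
#'
#' One set of canonical k-mers (lexicographic minimum of k-mer and reverse
#' complement) per reference label; k-mers containing N are skipped. Any
#' number of references can be supplied (organelle genomes, pathogens,
#' rRNA, ...).
#'
#' @param refs named character vector of FASTA paths, or a named list of
#'   DNAStringSet / character sequence vectors; names are the labels.
#' @param k odd k-mer size (default 31).
#' @return a [KmerIndex-class].
#' @export
buildKmerIndex <- function(refs, k = 31L) {
  k <- as.integer(k)
  if (length(refs) == 0) stop("empty reference set")
  if (k %% 2L == 0L) stop("k must be odd")
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("references must be named (label = sequences)")
  seqs <- lapply(refs, function(r) {
    if (is.character(r) && length(r) == 1 && file.exists(r))
      as.character(readFasta(r, "DNA"))
    else as.character(r)
  })
  shortest <- min(unlist(lapply(seqs, nchar)))
  if (k > shortest)
    stop("k (", k, ") exceeds the shortest reference length (", shortest, ")")
  sets <- lapply(seqs, cpp_kmer_set, k = k)
  for (l in names(sets))
    if (length(sets[[l]]) == 0)
      warning("reference '", l, "' yielded no k-mers (all N?)")
  new("KmerIndex", k = k, labels = names(refs), kmerSets = sets)
}

#' Classify reads (or read pairs) against a k-mer index
#'
#' A pair's k-mer hits are summed over both mates so mates never separate.
#' The winning label must be unique and collect at least `minFrac` of the
#' read's k-mer positions; a tied winner above threshold yields
#' `"ambiguous"`, anything else `"unclassified"` (including reads shorter
#' than k).
#'
#' @param r1 reads ([NucReads-class] or character).
#' @param r2 optional second mates.
#' @param index a [KmerIndex-class].
#' @param p a [classifyParams()] list.
#' @return character vector of labels with the hit fraction of the winner
#'   in `attr(, "frac")`.
#' @export
classifyReads <- function(r1, r2 = NULL, index, p = classifyParams()) {
  s1 <- if (is(r1, "NucReads")) r1@seq else as.character(r1)
  s2 <- if (is.null(r2)) character(0)
        else if (is(r2, "NucReads")) r2@seq else as.character(r2)
  r <- cpp_classify(s1, s2, index@labels, index@kmerSets, index@k,
                    p$minFrac)
  structure(r$label, frac = r$frac)
}

#' Split reads into per-reference FASTQ bins
#'
#' Writes one FASTQ (pair) per reference label plus the `unclassified`
#' bin -- the contaminant-free pass-through consumed by the downstream
#' stages -- and an `ambiguous` bin when ties occur. Bins are disjoint and
#' jointly exhaustive.
#'
#' @param r1,r2 mate streams as [NucReads-class] (`r2 = NULL` for
#'   single-end data).
#' @param index a [KmerIndex-class].
#' @param p a [classifyParams()] list.
#' @param outDir output directory (created).
#' @param prefix file-name prefix, typically the sample name.
#' @return invisibly, a list with `summary` (data.frame of label, count,
#'   fraction), `files`, and the per-pair `labels`.
#' @export
splitReads <- function(r1, r2 = NULL, index, p = classifyParams(),
                       outDir, prefix = "sample") {
  stopifnot(is(r1, "NucReads"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  labels <- classifyReads(r1, r2, index, p)
  bins <- c(index@labels, "ambiguous", "unclassified")
  bins <- bins[bins %in% c(labels, "unclassified")]
  files <- character(0)
  for (b in bins) {
    sel <- labels == b
    suffixes <- if (is.null(r2)) "" else c("_1", "_2")
    streams <- if (is.null(r2)) list(r1) else list(r1, r2)
    for (i in seq_along(streams)) {
      f <- file.path(outDir, paste0(prefix, "_", b, suffixes[i],
                                    ".fastq.gz"))
      writeFastq(streams[[i]][sel], f)
      files <- c(files, f)
    }
  }
  n <- length(labels)
  counts <- vapply(bins, function(b) sum(labels == b), integer(1))
  summary <- data.frame(label = bins, count = unname(counts),
                        fraction = unname(counts) / max(1L, n),
                        stringsAsFactors = FALSE)
  sf <- file.path(outDir, paste0(prefix, "_filter_summary.tsv"))
  write.table(summary, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(summary = summary, files = c(files, sf), labels = labels))
}
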