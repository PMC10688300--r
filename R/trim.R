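#' @include AllClasses.R seq-io.R
NULL

#' Trimming parameters
#'
#' Steps are applied per read in a fixed order: adapter clip, leading /
#' trailing low-quality clip, left-to-right sliding-window cut (at the
#' start of the first window whose mean Phred drops below `windowMinq`),
#' then the minimum-length gate. The defaults mirror common practice for
#' Illumina RNA-seq (window 4 at mean Q20, end clip at Q3, 36 bp floor).
#'
#' @param window sliding-window width (bases).
#' @param windowMinq minimum mean Phred inside a window.
#' @param leadQ,trailQ per-base thresholds for end clipping.
#' @param minLen minimum surviving read length.
#' @param adapters character vector of adapter sequences to clip (a read
#'   suffix matching an adapter prefix with at least `adapterMinOverlap`
#'   bases and at most `adapterMaxMismatch` mismatches, or any full
#'   internal occurrence, truncates the read).
#' @param adapterMinOverlap,adapterMaxMismatch adapter matching limits.
#' @return a validated parameter list of class `TrimParams`.
#' @export
trimParams <- function(window = 4L, windowMinq = 20, leadQ = 3L,
                       trailQ = 3L, minLen = 36L, adapters = character(0),
                       adapterMinOverlap = 8L, adapterMaxMismatch = 1L) {
  p <- list(window = as.integer(window), windowMinq = as.numeric(windowMinq),
            leadQ = as.integer(leadQ), trailQ = as.integer(trailQ),
            minLen = as.integer(minLen),
            adapters = toupper(as.character(adapters)),
            adapterMinOverlap = as.integer(adapterMinOverlap),
            adapterMaxMismatch = as.integer(adapterMaxMismatch))
  stopifnot(p$window >= 1L, p$minLen >= 1L, p$windowMinq >= 0,
            p$leadQ >= 0L, p$trailQ >= 0L, p$adapterMinOverlap >= 1L,
            p$adapterMaxMismatch >= 0L)
  structure(p, class = "TrimParams")
}

#' Quality- and adapter-trim reads
#'
#' @param reads a [NucReads-class] object with qualities.
#' @param p a [trimParams()] list.
#' @return list with `kept` (trimmed [NucReads-class]) and `discardedIds`.
#' @export
trimReads <- function(reads, p = trimParams()) {
  stopifnot(is(reads, "NucReads"), inherits(p, "TrimParams"))
  if (any(is.na(reads@qual)))
    stop("reads lack qualities; trimming requires FASTQ input ",
         "(use the FASTA-only entry points for quality-free data)")
  r <- cpp_trim_reads(reads@seq, reads@qual, p$adapters, p$window,
                      p$windowMinq, p$leadQ, p$trailQ, p$minLen,
                      p$adapterMinOverlap, p$adapterMaxMismatch)
  keep <- r$keep
  kept <- new("NucReads", id = reads@id[keep], seq = r$seq[keep],
              qual = r$qual[keep], mate = reads@mate[keep])
  list(kept = kept, discardedIds = reads@id[!keep])
}

#' Trim read pairs, preserving mate structure
#'
#' A pair survives into the paired outputs only when both mates survive;
#' a lone survivor goes to the orphans. Every input read ends up in
#' exactly one of paired, orphans or discarded.
#'
#' @param r1,r2 mate streams as [NucReads-class], aligned by record order.
#' @param p a [trimParams()] list.
#' @return list with `paired1`, `paired2`, `orphans` (all
#'   [NucReads-class]) and `discardedIds`.
#' @export
trimPairs <- function(r1, r2, p = trimParams()) {
  stopifnot(is(r1, "NucReads"), is(r2, "NucReads"))
  if (length(r1) != length(r2))
    stop("mate streams differ in length: ", length(r1), " vs ", length(r2))
  mism <- which(r1@id != r2@id)
  if (length(mism))
    stop("mate id mismatch at record ", mism[1], ": '", r1@id[mism[1]],
         "' vs '", r2@id[mism[1]], "'")
  t1 <- .trim_mask(r1, p)
  t2 <- .trim_mask(r2, p)
  both <- t1$keep & t2$keep
  only1 <- t1$keep & !t2$keep
  only2 <- !t1$keep & t2$keep
  sub <- function(reads, tr, sel) new("NucReads", id = reads@id[sel],
    seq = tr$seq[sel], qual = tr$qual[sel], mate = reads@mate[sel])
  orphans <- c(sub(r1, t1, only1), sub(r2, t2, only2))
  # restore record order across the two streams
  ord <- order(c(which(only1), which(only2)))
  list(paired1 = sub(r1, t1, both), paired2 = sub(r2, t2, both),
       orphans = orphans[ord],
       discardedIds = c(r1@id[!t1$keep], r2@id[!t2$keep]))
}

.trim_mask <- function(reads, p) {
  if (any(is.na(reads@qual)))
    stop("reads lack qualities; trimming requires FASTQ input")
  cpp_trim_reads(reads@seq, reads@qual, p$adapters, p$window, p$windowMinq,
                 p$leadQ, p$trailQ, p$minLen, p$adapterMinOverlap,
                 p$adapterMaxMismatch)
}
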