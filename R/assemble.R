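#' @include AllClasses.R
NULL

#' Targeted assembly parameters
#'
#' The assembler is a single-k de Bruijn unitig assembler intended for
#' the small, local read sets produced by recruitment; it does no
#' paired-end scaffolding or multi-k iteration. `minCount` doubles as the
#' error filter: k-mers supported by fewer reads are dropped before graph
#' construction, which (together with tip clipping) absorbs random
#' sequencing errors.
#'
#' @param k odd k-mer size, >= 15.
#' @param minCount k-mer count floor.
#' @param tipLen maximum tip length in nodes (default 2k).
#' @param bubbleIdentity sequence identity at or above which two
#'   single-entry/single-exit paths sharing both endpoints collapse onto
#'   the higher-coverage one.
#' @param minContigLen minimum reported contig length, bases.
#' @export
assemblyParams <- function(k = 31L, minCount = 2L, tipLen = 2L * k,
                           bubbleIdentity = 0.95, minContigLen = 200L) {
  p <- list(k = as.integer(k), minCount = as.integer(minCount),
            tipLen = as.integer(tipLen),
            bubbleIdentity = as.numeric(bubbleIdentity),
            minContigLen = as.integer(minContigLen))
  stopifnot(p$k >= 15L, p$k %% 2L == 1L, p$minCount >= 1L, p$tipLen >= 1L)
  structure(p, class = "AssemblyParams")
}

#' Count canonical k-mers of a read set
#'
#' @param reads [NucReads-class], [RecruitedReads-class], DNAStringSet or
#'   character sequences.
#' @param k odd k-mer size.
#' @return named integer vector, canonical k-mer -> count; k-mers
#'   containing N are skipped.
#' @export
countKmers <- function(reads, k) {
  seqs <- .read_seqs(reads)
  if (length(seqs) == 0) return(setNames(integer(0), character(0)))
  if (k > max(nchar(seqs)))
    stop("k (", k, ") exceeds the longest read length")
  r <- cpp_count_kmers(seqs, as.integer(k))
  setNames(r$count, r$kmer)
}

.read_seqs <- function(reads) {
  if (is(reads, "RecruitedReads"))
    c(reads@reads1@seq, if (!is.null(reads@reads2)) reads@reads2@seq)
  else if (is(reads, "NucReads")) reads@seq
  else as.character(reads)
}

#' Build the de Bruijn graph from k-mer counts
#'
#' Nodes are canonical k-mers with count >= `minCount`; edges are the
#' implicit k-1 overlaps. An empty graph is legal and yields no contigs.
#'
#' @param counts named integer vector from [countKmers()].
#' @param p an [assemblyParams()] list.
#' @return a [DeBruijnGraph-class].
#' @export
buildGraph <- function(counts, p = assemblyParams()) {
  keep <- counts >= p$minCount
  new("DeBruijnGraph", k = p$k, kmers = names(counts)[keep],
      counts = unname(as.numeric(counts[keep])))
}

#' In/out degrees of every graph node (canonical orientation)
#' @param g a [DeBruijnGraph-class].
#' @return integer matrix with rownames the k-mers and columns `in`/`out`.
#' @export
graphDegrees <- function(g) cpp_dbg_degrees(g@kmers, g@counts, g@k)

#' Clip tips from the graph
#'
#' Dead-end paths of at most `tipLen` nodes hanging off the rest of the
#' graph are removed, iterating to a fixed point. Isolated paths (both
#' ends dead) are legitimate short contigs and stay.
#'
#' @inheritParams graphDegrees
#' @param p an [assemblyParams()] list.
#' @export
clipTips <- function(g, p = assemblyParams()) {
  if (length(g@kmers) == 0) return(g)
  keep <- cpp_clip_tips(g@kmers, g@counts, g@k, p$tipLen)
  new("DeBruijnGraph", k = g@k, kmers = g@kmers[keep],
      counts = g@counts[keep])
}

#' Pop bubbles in the graph
#'
#' Two (or more) vertex-disjoint single-entry/single-exit paths sharing
#' both endpoint junctions and at least `bubbleIdentity` sequence identity
#' collapse onto the higher-mean-coverage path, iterating until stable.
#' Typical cause: heterozygous SNPs or lingering sequencing errors.
#'
#' @inheritParams clipTips
#' @export
popBubbles <- function(g, p = assemblyParams()) {
  if (length(g@kmers) == 0) return(g)
  keep <- cpp_pop_bubbles(g@kmers, g@counts, g@k, p$bubbleIdentity)
  new("DeBruijnGraph", k = g@k, kmers = g@kmers[keep],
      counts = g@counts[keep])
}

#' Spell contigs from the simplified graph
#'
#' Maximal non-branching paths, each reported once in canonical
#' orientation (the lexicographic minimum of the sequence and its reverse
#' complement), filtered by `minContigLen` and named `contig_N` in
#' deterministic order (length descending, then sequence).
#'
#' @inheritParams clipTips
#' @return a [Biostrings::DNAStringSet] with `mcols()$cov` holding each
#'   contig's mean k-mer count.
#' @export
graphContigs <- function(g, p = assemblyParams()) {
  empty <- DNAStringSet()
  if (length(g@kmers) == 0) return(empty)
  u <- cpp_dbg_unitigs(g@kmers, g@counts, g@k)
  if (length(u$seq) == 0) return(empty)
  rc <- as.character(cpp_revcomp(u$seq))
  seqs <- ifelse(u$seq <= rc, u$seq, rc)
  keep <- nchar(seqs) >= p$minContigLen
  seqs <- seqs[keep]; cov <- u$cov[keep]
  if (length(seqs) == 0) return(empty)
  ord <- order(-nchar(seqs), seqs)
  out <- DNAStringSet(setNames(seqs[ord],
                               paste0("contig_", seq_along(ord))))
  mcols(out)$cov <- cov[ord]
  out
}

#' Targeted de Bruijn assembly of a recruited read set
#'
#' Composition of [countKmers()], [buildGraph()], [clipTips()],
#' [popBubbles()] and [graphContigs()]; deterministic given reads and
#' parameters.
#'
#' @param reads a [RecruitedReads-class], [NucReads-class] or character
#'   sequences.
#' @param p an [assemblyParams()] list.
#' @return contig [Biostrings::DNAStringSet] (possibly empty) with mean
#'   coverage in `mcols()$cov`.
#' @export
assembleTargeted <- function(reads, p = assemblyParams()) {
  seqs <- .read_seqs(reads)
  if (length(seqs) == 0) return(DNAStringSet())
  counts <- countKmers(seqs, p$k)
  g <- buildGraph(counts, p)
  g <- clipTips(g, p)
  g <- popBubbles(g, p)
  graphContigs(g, p)
}
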