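#' @include AllClasses.R align.R genetic-code.R
NULL

#' Seed-and-extend parameters for translated read recruitment
#'
#' Reads are scored by exact amino-acid word hits between their six frame
#' translations and the query set, extended without gaps in both
#' directions under the scoring scheme, stopping once the running score
#' falls `xDrop` below its maximum. `minScore` is a raw substitution-score
#' threshold (no e-value statistics); following the principle that
#' recruitment should err on the permissive side, the default is low.
#'
#' @param aaWord exact amino-acid word size (>= 3).
#' @param minScore minimum extension score for a pair to be recruited.
#' @param xDrop extension drop-off.
#' @export
seedParams <- function(aaWord = 4L, minScore = 50L, xDrop = 20L) {
  p <- list(aaWord = as.integer(aaWord), minScore = as.integer(minScore),
            xDrop = as.integer(xDrop))
  stopifnot(p$aaWord >= 3L, p$minScore >= 0L, p$xDrop >= 0L)
  structure(p, class = "SeedParams")
}

#' Nucleotide k-mer enrichment parameters
#'
#' @param ntK odd nucleotide k-mer size for the enrichment pass.
#' @param minShared distinct canonical k-mers a pair must share with the
#'   seed-recruited set to be pulled in.
#' @export
enrichParams <- function(ntK = 25L, minShared = 2L) {
  p <- list(ntK = as.integer(ntK), minShared = as.integer(minShared))
  stopifnot(p$ntK %% 2L == 1L, p$minShared >= 1L)
  structure(p, class = "EnrichParams")
}

#' Index the exact amino-acid words of a query set
#'
#' @param queries AAStringSet or named character vector of protein queries.
#' @param p a [seedParams()] list.
#' @return named list: word -> data.frame(query id, 0-based offset).
#' @export
indexQueries <- function(queries, p = seedParams()) {
  qs <- .named_chr(queries)
  if (length(qs) == 0) stop("empty query set")
  ids <- if (is.null(names(qs))) as.character(seq_along(qs)) else names(qs)
  w <- p$aaWord
  short <- nchar(qs) < w
  if (any(short))
    warning("query ", paste(ids[short], collapse = ", "),
            " shorter than the word size; contributes no seeds")
  idx <- list()
  for (i in which(!short)) {
    offs <- 0:(nchar(qs[i]) - w)
    words <- substring(qs[i], offs + 1L, offs + w)
    ok <- !grepl("[X*]", words)
    for (j in which(ok)) {
      idx[[words[j]]] <- rbind(idx[[words[j]]],
        data.frame(query = ids[i], offset = offs[j],
                   stringsAsFactors = FALSE))
    }
  }
  idx
}

#' Score reads against a protein query set
#'
#' @param reads [NucReads-class] or character sequences.
#' @param queries protein queries (AAStringSet or character).
#' @param p a [seedParams()] list.
#' @param scheme a [ScoringScheme-class].
#' @param code genetic code used to translate the reads.
#' @return integer vector: best ungapped x-drop extension score per read
#'   (0 when no word hits).
#' @export
scoreReads <- function(reads, queries, p = seedParams(),
                       scheme = scoringScheme(), code = geneticCode(1L)) {
  seqs <- if (is(reads, "NucReads")) reads@seq else as.character(reads)
  qs <- .named_chr(queries)
  if (length(qs) == 0) stop("empty query set")
  cv <- .codon_vectors(code)
  cpp_score_reads(seqs, qs, p$aaWord, p$xDrop, scheme@matrix,
                  cv$codons, cv$aas)
}

#' Stage-1 recruitment: translated seeding
#'
#' A pair is recruited when either mate reaches `minScore`; both mates
#' enter the recruited set. Ids seen more than once are stored once.
#'
#' @param r1 first mates ([NucReads-class]).
#' @param r2 second mates, or `NULL` for single-end data.
#' @param queries protein query set.
#' @inheritParams scoreReads
#' @return a [RecruitedReads-class] with provenance `"seed"`.
#' @export
recruitSeed <- function(r1, r2 = NULL, queries, p = seedParams(),
                        scheme = scoringScheme(), code = geneticCode(1L)) {
  stopifnot(is(r1, "NucReads"))
  if (length(as.character(queries)) == 0) stop("empty query set")
  s1 <- scoreReads(r1, queries, p, scheme, code)
  best <- if (is.null(r2)) s1
          else pmax(s1, scoreReads(r2, queries, p, scheme, code))
  hit <- best >= p$minScore & best > 0L  # a pair needs at least one word hit
  sel <- which(hit & !duplicated(r1@id))
  prov <- setNames(rep("seed", length(sel)), r1@id[sel])
  new("RecruitedReads", reads1 = r1[sel],
      reads2 = if (is.null(r2)) NULL else r2[sel], provenance = prov)
}

#' Stage-2 recruitment: nucleotide k-mer enrichment
#'
#' Builds the canonical k-mer set of all stage-1 read sequences, rescans
#' the full read stream once, and pulls in any not-yet-recruited pair
#' sharing at least `minShared` distinct canonical k-mers with that set.
#' The union keeps ids unique; a single pass is performed.
#'
#' @param r1,r2 the full (trimmed/filtered) read streams.
#' @param stage1 the [RecruitedReads-class] from [recruitSeed()].
#' @param p an [enrichParams()] list.
#' @return a [RecruitedReads-class] containing stage 1 plus the enriched
#'   pairs (provenance `"enrich"`).
#' @export
enrichReads <- function(r1, r2 = NULL, stage1, p = enrichParams()) {
  stopifnot(is(stage1, "RecruitedReads"))
  if (length(stage1@reads1) == 0) return(stage1)
  pool <- c(stage1@reads1@seq,
            if (!is.null(stage1@reads2)) stage1@reads2@seq)
  kset <- cpp_kmer_set(pool, p$ntK)
  combined <- if (is.null(r2)) r1@seq else paste(r1@seq, r2@seq, sep = "N")
  shared <- cpp_shared_kmer_counts(combined, kset, p$ntK)
  newsel <- which(shared >= p$minShared &
                  !(r1@id %in% readIds(stage1@reads1)))
  newsel <- newsel[!duplicated(r1@id[newsel])]
  prov <- c(stage1@provenance,
            setNames(rep("enrich", length(newsel)), r1@id[newsel]))
  new("RecruitedReads",
      reads1 = c(stage1@reads1, r1[newsel]),
      reads2 = if (is.null(r2)) NULL else c(stage1@reads2, r2[newsel]),
      provenance = prov)
}
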