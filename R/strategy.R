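#' @include AllClasses.R align.R ini.R seq-io.R
NULL

#' Construct a search strategy
#'
#' A search strategy encapsulates everything needed to hunt one gene or
#' gene family: the protein query sources, how aggressively the query set
#' is pruned, the thresholds a transcript must meet to count as a match,
#' and the ORF parameters used in annotation.
#'
#' Query pruning identity is measured as matched alignment columns over
#' the shorter sequence; pruning keeps the longest representative of a
#' redundant cluster (longer queries recruit more read diversity).
#'
#' @param name strategy name (unique within a run).
#' @param queryFastaPaths protein FASTA file(s) supplying the queries.
#' @param minQueryLen,maxQueryLen query length range, amino acids.
#' @param dedupIdentity pairwise identity at or above which a query is
#'   considered redundant.
#' @param matchMinScore,matchMinIdentity,matchMinQcov minimum alignment
#'   score / identity / query coverage for a transcript to be retained.
#' @param orfMinLen,orfMaxLen ORF length range, amino acids.
#' @param startCodons accepted initiator codons.
#' @param allowPartialOrfs whether edge-truncated ORFs are reported.
#' @return a [SearchStrategy-class].
#' @export
searchStrategy <- function(name, queryFastaPaths = character(0),
                           minQueryLen = 10L, maxQueryLen = 100000L,
                           dedupIdentity = 0.98, matchMinScore = 60L,
                           matchMinIdentity = 0.40, matchMinQcov = 0.50,
                           orfMinLen = 30L, orfMaxLen = 100000L,
                           startCodons = "ATG", allowPartialOrfs = TRUE) {
  new("SearchStrategy", name = as.character(name),
      queryFastaPaths = as.character(queryFastaPaths),
      minQueryLen = as.integer(minQueryLen),
      maxQueryLen = as.integer(maxQueryLen),
      dedupIdentity = as.numeric(dedupIdentity),
      matchMinScore = as.integer(matchMinScore),
      matchMinIdentity = as.numeric(matchMinIdentity),
      matchMinQcov = as.numeric(matchMinQcov),
      orfMinLen = as.integer(orfMinLen), orfMaxLen = as.integer(orfMaxLen),
      startCodons = toupper(as.character(startCodons)),
      allowPartialOrfs = isTRUE(allowPartialOrfs))
}

.strategy_keys <- c(
  query_fasta_paths = "queryFastaPaths",
  min_query_len = "minQueryLen", max_query_len = "maxQueryLen",
  dedup_identity = "dedupIdentity", match_min_score = "matchMinScore",
  match_min_identity = "matchMinIdentity", match_min_qcov = "matchMinQcov",
  orf_min_len = "orfMinLen", orf_max_len = "orfMaxLen",
  start_codons = "startCodons", allow_partial_orfs = "allowPartialOrfs")

#' Parse a search-strategies configuration file
#'
#' INI dialect, one section per strategy; keys are the snake_case field
#' names of [searchStrategy()] (`query_fasta_paths`, `min_query_len`,
#' `max_query_len`, `dedup_identity`, `match_min_score`,
#' `match_min_identity`, `match_min_qcov`, `orf_min_len`, `orf_max_len`,
#' `start_codons`, `allow_partial_orfs`). Missing keys take the stated
#' defaults; unknown keys and unreadable query paths fail immediately.
#'
#' @param path configuration file path.
#' @return list of [SearchStrategy-class] objects, in file order.
#' @export
readSearchStrategies <- function(path) {
  ini <- .read_ini(path)
  if (length(ini) == 0) stop("no strategy sections in ", path)
  lapply(names(ini), function(nm) {
    sec <- ini[[nm]]
    unknown <- setdiff(names(sec), names(.strategy_keys))
    if (length(unknown))
      stop("unknown key(s) in strategy [", nm, "]: ",
           paste(unknown, collapse = ", "))
    args <- list(name = nm)
    for (key in names(sec)) {
      val <- sec[[key]]
      args[[.strategy_keys[[key]]]] <- switch(key,
        query_fasta_paths = .ini_paths(val),
        start_codons = .ini_paths(val),
        allow_partial_orfs = .ini_bool(val),
        min_query_len = , max_query_len = , match_min_score = ,
        orf_min_len = , orf_max_len = as.integer(val),
        as.numeric(val))
    }
    s <- do.call(searchStrategy, args)
    missing <- s@queryFastaPaths[!file.exists(s@queryFastaPaths)]
    if (length(missing))
      stop("strategy [", nm, "]: unreadable query path(s): ",
           paste(missing, collapse = ", "))
    s
  })
}

#' Build the pruned protein query set of a strategy
#'
#' Pools all sequences from the strategy's query FASTAs, strips terminal
#' stop characters, drops sequences outside the query length range, then
#' prunes greedily: sequences are visited longest first (ties by id) and a
#' sequence is accepted only if its identity to every already-accepted
#' sequence stays below `dedupIdentity`. Identity is matched columns over
#' the shorter sequence. Pfam / NCBI accession fetching is deliberately
#' not performed here; [queryFetchHook()] documents where a fetcher would
#' plug in.
#'
#' @param s a [SearchStrategy-class].
#' @param scheme a [ScoringScheme-class] for the identity alignments.
#' @return an [Biostrings::AAStringSet] in acceptance order.
#' @export
buildQuerySet <- function(s, scheme = scoringScheme()) {
  stopifnot(is(s, "SearchStrategy"))
  if (length(s@queryFastaPaths) == 0)
    stop("strategy '", s@name, "' supplies no query FASTA files")
  pool <- do.call(c, lapply(s@queryFastaPaths, readFasta, type = "AA"))
  if (length(pool) == 0)
    stop("strategy '", s@name, "': no query sequences found")
  seqs <- sub("\\*$", "", as.character(pool))
  ids <- names(pool)
  len <- nchar(seqs)
  inrange <- len >= s@minQueryLen & len <= s@maxQueryLen
  seqs <- seqs[inrange]; ids <- ids[inrange]; len <- len[inrange]
  ord <- order(-len, ids)
  accepted <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in accepted) {
      if (.global_identity(seqs[i], seqs[j], scheme) >= s@dedupIdentity) {
        dup <- TRUE
        break
      }
    }
    if (!dup) accepted <- c(accepted, i)
  }
  if (length(accepted) == 0)
    stop("strategy '", s@name, "': query set empty after pruning")
  AAStringSet(setNames(seqs[accepted], ids[accepted]))
}

#' Hook for remote query sources
#'
#' Pfam family and NCBI protein accessions or Entrez queries would be
#' resolved to FASTA files here before [buildQuerySet()] pools them;
#' network retrieval is out of scope for this package, so user-supplied
#' FASTA files are the sole query source and this stub only documents the
#' extension point.
#'
#' @param accessions character vector of remote identifiers.
#' @export
queryFetchHook <- function(accessions) {
  stop("remote query retrieval (Pfam/NCBI accessions) is not supported; ",
       "provide protein FASTA files via query_fasta_paths")
}
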