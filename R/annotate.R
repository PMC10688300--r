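#' @include AllClasses.R align.R genetic-code.R seq-io.R
NULL

#' Genomic source to genetic-code mapping
#'
#' Transcripts assembled from reads binned to an organellar reference are
#' translated under that organelle's code; everything else defaults to the
#' standard nuclear code. Plastid transcripts use the bacterial/plastid
#' table 11.
#'
#' @param nucleus,plastid,mitochondrion NCBI table ids.
#' @return named integer vector (a source-code map).
#' @export
sourceCodeMap <- function(nucleus = 1L, plastid = 11L, mitochondrion = 1L) {
  m <- c(nucleus = as.integer(nucleus), plastid = as.integer(plastid),
         mitochondrion = as.integer(mitochondrion))
  bad <- setdiff(m, geneticCodeIds())
  if (length(bad))
    stop("table id(s) not among the embedded genetic codes: ",
         paste(bad, collapse = ", "))
  m
}

#' @rdname sourceCodeMap
#' @param source one of the map's source names (e.g. "nucleus").
#' @param map a source-code map.
#' @return `geneticCodeFor` returns the [GeneticCode-class] assigned to
#'   the source.
#' @export
geneticCodeFor <- function(source, map = sourceCodeMap()) {
  if (!source %in% names(map))
    stop("unknown genomic source '", source, "' (expected one of: ",
         paste(names(map), collapse = ", "), ")")
  geneticCode(map[[source]])
}

#' Match assembled transcripts against the protein query set
#'
#' Each contig's six frame translations are locally aligned against every
#' query; the best alignment decides the contig's fate and strand. A
#' contig is retained when the best alignment reaches the strategy's
#' `matchMinScore`, `matchMinIdentity` and `matchMinQcov` at once.
#' User-provided transcriptomes pass through the same matching when
#' appended to `contigs`.
#'
#' @param contigs DNAStringSet or named character vector.
#' @param queries protein query set (AAStringSet or named character).
#' @param s a [SearchStrategy-class] providing the thresholds.
#' @param scheme a [ScoringScheme-class].
#' @param code genetic code for the translations.
#' @return data.frame (possibly empty): contig, query, score, identity,
#'   qCov, strand, frame.
#' @export
matchTranscripts <- function(contigs, queries, s, scheme = scoringScheme(),
                             code = geneticCode(1L)) {
  cs <- .named_chr(contigs)
  qs <- .named_chr(queries)
  if (length(cs) == 0 || length(qs) == 0)
    stop("contigs and queries must be non-empty")
  if (is.null(names(cs))) names(cs) <- paste0("contig_", seq_along(cs))
  qids <- if (is.null(names(qs))) as.character(seq_along(qs)) else names(qs)
  rows <- lapply(names(cs), function(cid) {
    frames <- sixFrame(cs[[cid]], code)
    best <- NULL
    for (fi in seq_len(nrow(frames))) {
      if (nchar(frames$aa[fi]) == 0) next
      for (qi in seq_along(qs)) {
        r <- cpp_smith_waterman(qs[[qi]], frames$aa[fi], scheme@matrix,
                                scheme@gapOpen, scheme@gapExtend)
        if (is.null(best) || r$score > best$score) {
          best <- r
          best$strand <- frames$strand[fi]
          best$frame <- frames$frame[fi]
          best$query <- qids[qi]
          best$qlen <- nchar(qs[[qi]])
        }
      }
    }
    if (is.null(best)) return(NULL)
    identity <- if (best$columns > 0) best$matches / best$columns else 0
    qcov <- (best$q_end - best$q_start) / best$qlen
    if (best$score < s@matchMinScore || identity < s@matchMinIdentity ||
        qcov < s@matchMinQcov) return(NULL)
    data.frame(contig = cid, query = best$query, score = best$score,
               identity = identity, qCov = qcov, strand = best$strand,
               frame = best$frame, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(contig = character(0), query = character(0),
                      score = integer(0), identity = numeric(0),
                      qCov = numeric(0), strand = character(0),
                      frame = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Locate and classify open reading frames on one contig
#'
#' Scans the three frames of the given strand. Complete ORFs run from a
#' start codon to a stop (stop codon included in the span, excluded from
#' the peptide; nested starts sharing a stop yield only the longest).
#' When no start precedes the first stop of a frame, the in-frame stretch
#' from the contig edge is reported as 5'-partial (only if
#' `allowPartialOrfs`); a start codon without a downstream stop yields a
#' 3'-partial; a frame with neither start nor stop is one edge-to-edge
#' "internal" ORF. ORFs never begin at an X (N-containing codon); the
#' peptide length must lie within the strategy's ORF range. Coordinates
#' are 0-based half-open on the contig's forward strand.
#'
#' @param seq contig sequence (single string).
#' @param strand "+" or "-": the strand to scan (known from the protein
#'   match).
#' @param code a [GeneticCode-class].
#' @param s a [SearchStrategy-class] (ORF parameters).
#' @return data.frame: start, end, strand, frame, completeness, aa.
#' @export
findOrfs <- function(seq, strand = "+", code = geneticCode(1L), s) {
  stopifnot(length(seq) == 1, strand %in% c("+", "-"),
            is(s, "SearchStrategy"))
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  rs <- if (strand == "+") seq else revComp(seq)
  map <- code@codonToAa
  out <- list()
  emit <- function(a, e, f, completeness, aa) {
    # a, e: first/last codon index (1-based) on the reading strand;
    # e includes the stop codon for stop-terminated classes
    ntStart <- f + 3L * (a - 1L)
    ntEnd <- f + 3L * e
    if (strand == "-") {
      tmp <- L - ntEnd
      ntEnd <- L - ntStart
      ntStart <- tmp
    }
    out[[length(out) + 1L]] <<- data.frame(
      start = ntStart, end = ntEnd, strand = strand, frame = f,
      completeness = completeness, aa = aa, stringsAsFactors = FALSE)
  }
  for (f in 0:2) {
    ncod <- (L - f) %/% 3L
    if (ncod < 1L) next
    st <- f + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(rs, st, st + 2L)
    aavec <- unname(map[codons])
    aavec[is.na(aavec)] <- "X"
    isstart <- codons %in% s@startCodons
    stops <- which(aavec == "*")
    begins <- c(1L, stops + 1L)
    ends <- c(stops, ncod)
    for (gi in seq_along(begins)) {
      b <- begins[gi]; e <- ends[gi]
      if (b > e) next  # stop codon at the contig edge leaves no segment
      hasStop <- e %in% stops
      cod_hi <- if (hasStop) e - 1L else e
      starts_in <- if (cod_hi >= b) b - 1L + which(isstart[b:cod_hi])
                   else integer(0)
      if (hasStop) {
        if (length(starts_in)) {
          a <- starts_in[1]
          aa <- aavec[a:cod_hi]
          aa[1] <- "M"  # initiator convention
          if (length(aa) >= s@orfMinLen && length(aa) <= s@orfMaxLen)
            emit(a, e, f, "complete", paste(aa, collapse = ""))
        } else if (b == 1L && s@allowPartialOrfs && cod_hi >= b) {
          a0 <- b - 1L + which(aavec[b:cod_hi] != "X")[1]
          if (!is.na(a0)) {
            aa <- aavec[a0:cod_hi]
            if (length(aa) >= s@orfMinLen && length(aa) <= s@orfMaxLen)
              emit(a0, e, f, "5prime_partial", paste(aa, collapse = ""))
          }
        }
      } else {
        if (length(starts_in)) {
          a <- starts_in[1]
          aa <- aavec[a:e]
          aa[1] <- "M"
          if (length(aa) >= s@orfMinLen && length(aa) <= s@orfMaxLen)
            emit(a, e, f, "3prime_partial", paste(aa, collapse = ""))
        } else if (b == 1L) {
          a0 <- b - 1L + which(aavec[b:e] != "X")[1]
          if (!is.na(a0)) {
            aa <- aavec[a0:e]
            if (length(aa) >= s@orfMinLen && length(aa) <= s@orfMaxLen)
              emit(a0, e, f, "internal", paste(aa, collapse = ""))
          }
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      completeness = character(0), aa = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Select the coding sequence among a contig's ORFs
#'
#' Each ORF is scored by its best local alignment against the query set
#' (with no queries, by peptide length, so the longest ORF wins). Ties
#' fall to completeness (complete over partial over internal), then to
#' the longer peptide, then to the smaller start coordinate. Exactly one
#' CDS per contig.
#'
#' @param orfs data.frame from [findOrfs()].
#' @param queries protein query set (may be empty/NULL for control mode).
#' @param scheme a [ScoringScheme-class].
#' @return the winning ORF row with `score` (and `query` when scored
#'   against queries) filled; NULL when `orfs` is empty.
#' @export
selectCds <- function(orfs, queries = NULL, scheme = scoringScheme()) {
  if (is.null(orfs) || nrow(orfs) == 0) return(NULL)
  qs <- if (is.null(queries)) character(0) else .named_chr(queries)
  if (length(qs) == 0) {
    orfs$score <- nchar(orfs$aa)
    orfs$query <- NA_character_
  } else {
    qids <- if (is.null(names(qs))) as.character(seq_along(qs))
            else names(qs)
    sc <- vapply(orfs$aa, function(a) {
      vapply(qs, function(q)
        cpp_smith_waterman(a, q, scheme@matrix, scheme@gapOpen,
                           scheme@gapExtend)$score, numeric(1))
    }, numeric(length(qs)))
    sc <- matrix(sc, nrow = length(qs))
    best_q <- apply(sc, 2, which.max)
    orfs$score <- apply(sc, 2, max)
    orfs$query <- qids[best_q]
  }
  rank <- c(complete = 3L, "5prime_partial" = 2L, "3prime_partial" = 2L,
            internal = 1L)
  ord <- order(-orfs$score, -rank[orfs$completeness], -nchar(orfs$aa),
               orfs$start)
  orfs[ord[1], , drop = FALSE]
}

#' Annotate assembled contigs
#'
#' Retains contigs matching the query set, scans the matched strand for
#' ORFs, and selects one CDS per contig. Contigs whose ORF scan comes up
#' empty are kept in the transcript output without a CDS (with a
#' message).
#'
#' @inheritParams matchTranscripts
#' @return list with `matches`, `orfs` (all ORFs, with a contig column)
#'   and `cds` (one row per contig with a CDS).
#' @export
annotateContigs <- function(contigs, queries, s, scheme = scoringScheme(),
                            code = geneticCode(1L)) {
  cs <- .named_chr(contigs)
  if (is.null(names(cs))) names(cs) <- paste0("contig_", seq_along(cs))
  matches <- matchTranscripts(cs, queries, s, scheme, code)
  orfs_all <- list()
  cds_all <- list()
  for (i in seq_len(nrow(matches))) {
    cid <- matches$contig[i]
    orfs <- findOrfs(cs[[cid]], matches$strand[i], code, s)
    if (nrow(orfs)) orfs$contig <- cid
    orfs_all[[cid]] <- orfs
    cds <- selectCds(orfs, queries, scheme)
    if (is.null(cds)) {
      message("contig ", cid, ": no ORF passed the filters; ",
              "transcript reported without CDS")
    } else {
      cds$contig <- cid
      cds_all[[cid]] <- cds
    }
  }
  list(matches = matches,
       orfs = if (length(orfs_all)) do.call(rbind, c(orfs_all,
                 make.row.names = FALSE)) else NULL,
       cds = if (length(cds_all)) do.call(rbind, c(cds_all,
                 make.row.names = FALSE)) else NULL)
}

.gff_phase <- function(completeness, frame) {
  ifelse(completeness == "5prime_partial", (3L - (frame %% 3L)) %% 3L, 0L)
}

#' Write the four annotation output files
#'
#' Produces, per strategy directory: `transcripts.fasta` (matched
#' transcripts), `transcripts.gff3` (one mRNA per transcript, one CDS per
#' selected ORF; 1-based inclusive coordinates, CDS phase 0 for complete
#' ORFs and `(3 - overhang mod 3) mod 3` for 5'-partials), `orfs_nt.fasta`
#' (CDS extracted from the forward strand, reverse-complemented for minus
#' matches) and `orfs_aa.fasta`. The amino-acid FASTA is the hand-off
#' point for downstream functional annotation tools.
#'
#' @param contigs DNAStringSet or named character (superset containing the
#'   matched contigs).
#' @param matches data.frame from [matchTranscripts()].
#' @param cds data.frame of selected CDS rows (from [annotateContigs()]).
#' @param outDir output directory (created).
#' @return invisibly, the four file paths.
#' @export
writeAnnotation <- function(contigs, matches, cds, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cs <- .named_chr(contigs)
  if (is.null(names(cs))) names(cs) <- paste0("contig_", seq_along(cs))
  if (is.null(matches) || nrow(matches) == 0) {
    writeFasta(DNAStringSet(), file.path(outDir, "transcripts.fasta"))
    writeLines("##gff-version 3", file.path(outDir, "transcripts.gff3"))
    writeFasta(DNAStringSet(), file.path(outDir, "orfs_nt.fasta"))
    writeFasta(AAStringSet(), file.path(outDir, "orfs_aa.fasta"))
    return(invisible(file.path(outDir, c("transcripts.fasta",
      "transcripts.gff3", "orfs_nt.fasta", "orfs_aa.fasta"))))
  }
  kept <- cs[matches$contig]
  f_tr <- file.path(outDir, "transcripts.fasta")
  f_gff <- file.path(outDir, "transcripts.gff3")
  f_nt <- file.path(outDir, "orfs_nt.fasta")
  f_aa <- file.path(outDir, "orfs_aa.fasta")
  writeFasta(DNAStringSet(kept), f_tr)

  grs <- GRanges(seqnames = matches$contig,
                 ranges = IRanges(1L, nchar(kept)),
                 strand = matches$strand)
  grs$type <- "mRNA"
  grs$ID <- matches$contig
  grs$Parent <- NA_character_
  grs$score <- as.numeric(matches$score)
  grs$completeness <- NA_character_
  grs$phase <- NA_integer_
  if (!is.null(cds) && nrow(cds)) {
    grc <- GRanges(seqnames = cds$contig,
                   ranges = IRanges(cds$start + 1L, cds$end),
                   strand = cds$strand)
    grc$type <- "CDS"
    grc$ID <- paste0(cds$contig, ".cds")
    grc$Parent <- cds$contig
    grc$score <- as.numeric(cds$score)
    grc$completeness <- cds$completeness
    grc$phase <- .gff_phase(cds$completeness, cds$frame)
    grs <- c(grs, grc)
    nt <- substring(cs[cds$contig], cds$start + 1L, cds$end)
    nt <- ifelse(cds$strand == "-", as.character(revComp(nt)), nt)
    orf_ids <- paste0(cds$contig, ".cds")
    nts <- DNAStringSet(setNames(nt, orf_ids))
    mcols(nts)$description <- cds$completeness
    writeFasta(nts, f_nt)
    writeFasta(AAStringSet(setNames(cds$aa, orf_ids)), f_aa)
  } else {
    writeFasta(DNAStringSet(), f_nt)
    writeFasta(AAStringSet(), f_aa)
  }
  rtracklayer::export(grs, f_gff, format = "gff3")
  invisible(c(transcripts = f_tr, gff3 = f_gff, orfs_nt = f_nt,
              orfs_aa = f_aa))
}
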