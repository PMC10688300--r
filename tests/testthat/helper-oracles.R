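# Independent oracles and small fixture builders shared by the tests.
# Oracles are deliberately written as plain brute force, separate from the
# package's implementations.

suppressPackageStartupMessages(library(Biostrings))

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
rand_aa <- function(n) paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV",
                                             "")[[1]], n, TRUE),
                             collapse = "")

const_qual <- function(n, q = 40L) intToUtf8(rep(q + 33L, n))

# local alignment score oracle: Biostrings dynamic programming
sw_oracle_score <- function(a, b, open = 11, ext = 1) {
  m <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = open,
    gapExtension = ext)
  max(0, BiocGenerics::score(m))
}

# sliding-window trim oracle (lead/trail/adapters assumed off): cut at
# the first failing window's start, then keep individually good bases
window_cut_oracle <- function(quals, window, minq) {
  n <- length(quals)
  if (n < window) return(n)
  cut <- n
  for (st in 1:(n - window + 1)) {
    if (mean(quals[st:(st + window - 1)]) < minq) { cut <- st - 1L; break }
  }
  while (cut < n && quals[cut + 1L] >= minq) cut <- cut + 1L
  cut
}

# brute-force ORF enumerator: checks every codon-aligned candidate span
# against the classification rules directly.
orf_oracle <- function(seq, strand, code_map, start_codons, min_aa, max_aa,
                       allow_partial = TRUE) {
  L <- nchar(seq)
  rs <- if (strand == "+") seq else
    as.character(reverseComplement(DNAString(seq)))
  res <- list()
  for (f in 0:2) {
    ncod <- (L - f) %/% 3
    if (ncod < 1) next
    pos <- f + 1 + 3 * (0:(ncod - 1))
    cods <- substring(rs, pos, pos + 2)
    aa <- unname(code_map[cods])
    aa[is.na(aa)] <- "X"
    is_stop <- aa == "*"
    is_start <- cods %in% start_codons
    add <- function(a, e, cls, pep) {
      if (nchar(pep) < min_aa || nchar(pep) > max_aa) return()
      nt0 <- f + 3 * (a - 1); nt1 <- f + 3 * e
      if (strand == "-") { t <- L - nt1; nt1 <- L - nt0; nt0 <- t }
      res[[length(res) + 1]] <<- data.frame(
        start = as.integer(nt0), end = as.integer(nt1),
        strand = strand, frame = as.integer(f),
        completeness = cls, aa = pep, stringsAsFactors = FALSE)
    }
    for (e in which(is_stop)) {
      # candidate complete ORFs ending at this stop: earliest start with
      # no intervening stop
      a <- NA
      if (e > 1) for (i in (e - 1):1) {
        if (is_stop[i]) break
        if (is_start[i]) a <- i
      }
      if (!is.na(a)) {
        pep <- aa[a:(e - 1)]; pep[1] <- "M"
        add(a, e, "complete", paste(pep, collapse = ""))
      } else if (allow_partial && !any(is_stop[seq_len(e - 1)])) {
        # no start before the first stop: 5'-partial from the edge
        a0 <- which(aa[seq_len(max(0, e - 1))] != "X")[1]
        if (!is.na(a0))
          add(a0, e, "5prime_partial",
              paste(aa[a0:(e - 1)], collapse = ""))
      }
    }
    last_stop <- if (any(is_stop)) max(which(is_stop)) else 0
    tail_idx <- if (last_stop < ncod) (last_stop + 1):ncod else integer(0)
    if (length(tail_idx)) {
      st_in <- tail_idx[is_start[tail_idx]]
      if (length(st_in)) {
        a <- st_in[1]
        pep <- aa[a:ncod]; pep[1] <- "M"
        add(a, ncod, "3prime_partial", paste(pep, collapse = ""))
      } else if (last_stop == 0) {
        a0 <- which(aa != "X")[1]
        if (!is.na(a0))
          add(a0, ncod, "internal", paste(aa[a0:ncod], collapse = ""))
      }
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      completeness = character(0), aa = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

sort_orfs <- function(d) {
  d <- d[order(d$frame, d$start, d$end, d$completeness), ,
         drop = FALSE]
  rownames(d) <- NULL
  d[, c("start", "end", "strand", "frame", "completeness", "aa")]
}

# naive k-mer count oracle over canonical k-mers
count_kmers_oracle <- function(seqs, k) {
  all <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1), k:n)
    km <- km[!grepl("N", km)]
    rc <- as.character(reverseComplement(DNAStringSet(km)))
    all <- c(all, pmin(km, rc))
  }
  table(all)
}

write_tmp_fasta <- function(seqs, ext = ".fasta") {
  f <- tempfile(fileext = ext)
  writeXStringSet(if (is.character(seqs)) BStringSet(seqs) else seqs, f)
  f
}

# mutate a protein to a given approximate identity (substitutions only)
mutate_protein <- function(p, identity) {
  chars <- strsplit(p, "")[[1]]
  nmut <- round(length(chars) * (1 - identity))
  idx <- sample(seq_along(chars), nmut)
  pool <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in idx) chars[i] <- sample(setdiff(pool, chars[i]), 1)
  paste(chars, collapse = "")
}
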