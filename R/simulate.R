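#' @include AllClasses.R genetic-code.R seq-io.R
NULL

#' Simulation parameters
#'
#' Emulates a stranded paired-end Illumina mRNA-seq experiment at desk
#' scale: one planted target transcript (5'UTR + back-translated CDS +
#' 3'UTR) among random background transcripts, optional organellar
#' contamination, 150 bp pairs at 30x coverage with a 1% uniform
#' substitution error rate and no indels. Substitution errors are silent:
#' base qualities are drawn Normal(38, 2) (clipped to [2, 41]) regardless
#' of whether a base is erroneous, as in real data.
#'
#' @param seed integer seed; all generator randomness derives from it
#'   (R's Mersenne-Twister RNG).
#' @param nBackground number of random background transcripts.
#' @param backgroundLen length range of background transcripts, bases.
#' @param targetProtein planted protein (character/AAString); defaults to
#'   a seeded random 300-residue protein starting with M.
#' @param utrLen UTR length range per side, bases.
#' @param readLen read length, bases.
#' @param insertMean,insertSd insert-size distribution (Normal, truncated
#'   below at `readLen`).
#' @param coverage per-transcript fold coverage.
#' @param errorRate per-base substitution probability, in [0, 0.25].
#' @param organelleLen length of the simulated organelle genome.
#' @return parameter list of class `SimParams`.
#' @export
simParams <- function(seed = 1L, nBackground = 50L,
                      backgroundLen = c(500L, 3000L), targetProtein = NULL,
                      utrLen = c(50L, 300L), readLen = 150L,
                      insertMean = 350, insertSd = 50, coverage = 30,
                      errorRate = 0.01, organelleLen = 10000L) {
  p <- list(seed = as.integer(seed), nBackground = as.integer(nBackground),
            backgroundLen = as.integer(backgroundLen),
            targetProtein = if (is.null(targetProtein)) NULL
                            else as.character(targetProtein),
            utrLen = as.integer(utrLen), readLen = as.integer(readLen),
            insertMean = as.numeric(insertMean),
            insertSd = as.numeric(insertSd),
            coverage = as.numeric(coverage),
            errorRate = as.numeric(errorRate),
            organelleLen = as.integer(organelleLen))
  stopifnot(p$nBackground >= 0L, all(p$backgroundLen > 0L),
            p$readLen > 0L, p$insertMean > 0, p$insertSd >= 0,
            p$coverage > 0, p$errorRate >= 0, p$errorRate <= 0.25,
            p$organelleLen > 0L)
  structure(p, class = "SimParams")
}

#' Seeded random protein
#'
#' Uniform over the 20 standard residues, starting with M (so the planted
#' CDS opens with an initiator codon).
#' @param n protein length in residues.
#' @param seed optional seed (uses the current RNG state when NULL).
#' @export
randomProtein <- function(n = 300L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  paste(c("M", sample(aas, n - 1L, replace = TRUE)), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Back-translate a protein into a coding sequence
#'
#' Each residue is mapped to a uniformly chosen synonymous codon of the
#' given code, and a stop codon is appended; translating the result
#' reproduces the protein (plus the terminal `*`). Codon usage bias can be
#' layered on by supplying weighted sampling externally.
#'
#' @param protein amino-acid string without internal stops.
#' @param code a [GeneticCode-class].
#' @param seed optional seed.
#' @return nucleotide CDS string.
#' @export
backtranslate <- function(protein, code = geneticCode(1L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  protein <- as.character(protein)
  res <- strsplit(protein, "")[[1]]
  if (any(res[-length(res)] == "*"))
    stop("protein contains an internal stop")
  by_aa <- split(names(code@codonToAa), code@codonToAa)
  pick <- function(aa) {
    cods <- by_aa[[aa]]
    if (is.null(cods)) stop("no codon for residue '", aa, "'")
    cods[sample.int(length(cods), 1L)]
  }
  paste(c(vapply(res, pick, character(1)),
          pick("*")), collapse = "")
}

#' Generate a synthetic transcriptome with one planted target
#'
#' Background transcripts are uniform random sequence; the target is
#' 5'UTR + back-translated CDS + 3'UTR with UTR lengths drawn from
#' `utrLen`. The returned truth records the planted CDS coordinates
#' (0-based half-open) and protein.
#'
#' @param p a [simParams()] list.
#' @return list with `transcripts` (DNAStringSet) and `truth`.
#' @export
makeTranscriptome <- function(p = simParams()) {
  set.seed(p$seed)
  protein <- if (is.null(p$targetProtein)) randomProtein(300L)
             else p$targetProtein
  bg_len <- sample(p$backgroundLen[1]:p$backgroundLen[2], p$nBackground,
                   replace = TRUE)
  bg <- vapply(bg_len, .random_dna, character(1))
  names(bg) <- if (p$nBackground > 0)
    paste0("background_", seq_len(p$nBackground)) else character(0)
  cds <- backtranslate(protein)
  u5 <- sample(p$utrLen[1]:p$utrLen[2], 1L)
  u3 <- sample(p$utrLen[1]:p$utrLen[2], 1L)
  # Close the reading frame immediately upstream of the planted start (as
  # real 5'UTRs nearly always do), so the planted CDS is the longest
  # complete ORF in its frame and the ground truth is unambiguous.
  utr5 <- paste0(.random_dna(u5 - 3L), "TAA")
  target <- paste0(utr5, cds, .random_dna(u3))
  seqs <- c(bg, target = target)
  truth <- list(targetId = "target", protein = protein,
                cdsStart = u5, cdsEnd = u5 + nchar(cds),
                targetSeq = target)
  list(transcripts = DNAStringSet(seqs), truth = truth)
}

#' Simulate paired-end reads from transcripts
#'
#' Fragments are drawn per transcript to reach the target coverage;
#' insert lengths are Normal(`insertMean`, `insertSd`) truncated to
#' [readLen, transcript length]; mate 1 is the fragment's 5' end, mate 2
#' the reverse complement of its 3' end. Substitutions are i.i.d. at
#' `errorRate`.
#'
#' @param transcripts DNAStringSet or named character vector.
#' @param p a [simParams()] list.
#' @param seed seed for the read-level randomness (default derived from
#'   `p$seed` so transcriptome and reads can be generated independently).
#' @param origins optional per-transcript origin labels for the manifest
#'   (default: the transcript names).
#' @return list with `reads1`, `reads2` ([NucReads-class]) and `manifest`
#'   (data.frame id, origin; one row per pair).
#' @export
simulateReads <- function(transcripts, p = simParams(),
                          seed = p$seed + 1L, origins = NULL) {
  seqs <- .named_chr(transcripts)
  stopifnot(length(seqs) > 0)
  if (is.null(names(seqs))) names(seqs) <- paste0("tx_", seq_along(seqs))
  if (is.null(origins)) origins <- names(seqs)
  set.seed(seed)
  rl <- p$readLen
  id1 <- character(0); s1 <- character(0)
  id2 <- character(0); s2 <- character(0)
  origin <- character(0)
  for (ti in seq_along(seqs)) {
    L <- nchar(seqs[[ti]])
    if (L < rl) next
    np <- max(0L, round(p$coverage * L / (2 * rl)))
    if (np == 0L) next
    ins <- round(rnorm(np, p$insertMean, p$insertSd))
    ins <- pmin(pmax(ins, rl), L)
    st <- vapply(ins, function(i) sample.int(L - i + 1L, 1L) - 1L,
                 numeric(1))
    frag <- substring(seqs[[ti]], st + 1L, st + ins)
    m1 <- substring(frag, 1L, rl)
    m2 <- as.character(cpp_revcomp(substring(frag, ins - rl + 1L, ins)))
    s1 <- c(s1, m1); s2 <- c(s2, m2)
    origin <- c(origin, rep(origins[ti], np))
  }
  n <- length(s1)
  ids <- sprintf("r%06d", seq_len(n))
  mutate <- function(seqs) {
    if (p$errorRate <= 0 || length(seqs) == 0) return(seqs)
    mat <- matrix(runif(length(seqs) * rl) < p$errorRate,
                  nrow = length(seqs))
    hit <- which(rowSums(mat) > 0)
    for (i in hit) {
      chars <- strsplit(seqs[i], "")[[1]]
      for (j in which(mat[i, seq_along(chars)])) {
        chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    seqs
  }
  s1 <- mutate(s1); s2 <- mutate(s2)
  qual <- function(k) {
    q <- matrix(pmin(pmax(round(rnorm(k * rl, 38, 2)), 2L), 41L) + 33L,
                nrow = k)
    vapply(seq_len(k), function(i) intToUtf8(q[i, ]), character(1))
  }
  list(reads1 = NucReads(ids, s1, qual(n), 1L),
       reads2 = NucReads(ids, s2, qual(n), 2L),
       manifest = data.frame(id = ids, origin = origin,
                             stringsAsFactors = FALSE))
}

#' Generate a complete synthetic project on disk
#'
#' Writes paired FASTQ (gzip), the organelle reference FASTA, the target
#' protein FASTA, the true transcripts, and a `truth.json` manifest
#' recording each read pair's origin and the planted CDS.
#'
#' @param p a [simParams()] list.
#' @param outDir output directory (created).
#' @param organelle include reads from a simulated organelle genome.
#' @return invisibly, a list with the file paths and the truth object.
#' @export
simulateDataset <- function(p = simParams(), outDir, organelle = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tx <- makeTranscriptome(p)
  seqs <- as.character(tx$transcripts)
  origins <- names(seqs)
  origins[origins == tx$truth$targetId] <- "target"
  if (organelle) {
    org <- .random_dna(p$organelleLen)  # RNG continues from makeTranscriptome
    seqs <- c(seqs, organelle = org)
    origins <- c(origins, "organelle")
  }
  sim <- simulateReads(seqs, p, seed = p$seed + 1L, origins = origins)
  paths <- list(
    reads1 = file.path(outDir, "reads_1.fastq.gz"),
    reads2 = file.path(outDir, "reads_2.fastq.gz"),
    organelle = if (organelle) file.path(outDir, "organelle.fasta"),
    protein = file.path(outDir, "target_protein.fasta"),
    transcripts = file.path(outDir, "true_transcripts.fasta"),
    truth = file.path(outDir, "truth.json"))
  writeFastq(sim$reads1, paths$reads1)
  writeFastq(sim$reads2, paths$reads2)
  if (organelle)
    writeFasta(DNAStringSet(c(organelle = seqs[["organelle"]])),
               paths$organelle)
  writeFasta(AAStringSet(c(target_protein = tx$truth$protein)),
             paths$protein)
  writeFasta(tx$transcripts, paths$transcripts)
  truth <- c(tx$truth[c("targetId", "protein", "cdsStart", "cdsEnd",
                        "targetSeq")],
             list(manifest = sim$manifest))
  write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth, reads1 = sim$reads1,
                 reads2 = sim$reads2))
}
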