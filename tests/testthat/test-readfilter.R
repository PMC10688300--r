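test_that("index construction canonicalizes k-mers and respects bounds", {
  set.seed(21)
  ref <- rand_dna(40)
  idx <- buildKmerIndex(list(a = ref), k = 31)
  expect_lte(length(idx@kmerSets$a), 10)
  # a reference and its reverse complement index identically
  idx2 <- buildKmerIndex(list(fwd = ref, rev = as.character(revComp(ref))),
                         k = 31)
  expect_identical(idx2@kmerSets$fwd, idx2@kmerSets$rev)
  expect_error(buildKmerIndex(list(), 31), "empty")
  expect_error(buildKmerIndex(list(a = ref), 30), "odd")
  expect_error(buildKmerIndex(list(a = "ACGT"), 31), "shortest reference")
  expect_warning(buildKmerIndex(list(n = strrep("N", 100)), 31), "no k-mers")
})

test_that("reads copied from a reference classify to it; random reads do not", {
  set.seed(22)
  refA <- rand_dna(10000)
  idx <- buildKmerIndex(list(A = refA), k = 31)
  # verbatim copies
  pos <- sample(1:(10000 - 150), 50)
  copies <- substring(refA, pos, pos + 149)
  expect_true(all(classifyReads(copies, index = idx) == "A"))
  # reverse-complemented copies classify identically (canonical k-mers)
  expect_true(all(classifyReads(as.character(revComp(copies)),
                                index = idx) == "A"))
  # random 150-base reads: expected k-mer collisions ~ 10^4 * 120 / 4^31,
  # effectively zero
  rnd <- vapply(rep(150, 1000), rand_dna, character(1))
  expect_true(all(classifyReads(rnd, index = idx) == "unclassified"))
  # reads shorter than k are unclassified, not an error
  expect_identical(classifyReads("ACGTACGT", index = idx),
                   structure("unclassified", frac = 0))
})

test_that("a read split equally between two references is ambiguous", {
  set.seed(23)
  refA <- rand_dna(5000); refB <- rand_dna(5000)
  idx <- buildKmerIndex(list(A = refA, B = refB), k = 31)
  # join the end of A to the start of B: junction k-mers then exist in
  # neither reference (no sequence continues past either boundary)
  half <- paste0(substr(refA, 4920, 5000), substr(refB, 1, 81))
  # brute-force recount of per-label hits to confirm the tie
  hitsA <- sum(names(count_kmers_oracle(half, 31)) %in% idx@kmerSets$A)
  hitsB <- sum(names(count_kmers_oracle(half, 31)) %in% idx@kmerSets$B)
  expect_identical(hitsA, hitsB)
  expect_identical(unclass(classifyReads(half, index = idx))[1], "ambiguous")
})

test_that("paired classification sums hits over both mates", {
  set.seed(24)
  refA <- rand_dna(5000)
  idx <- buildKmerIndex(list(A = refA), k = 31)
  m1 <- substring(refA, 201, 350)
  m2 <- rand_dna(150)  # mate 2 alone would be unclassified
  lab <- classifyReads(m1, m2, idx, classifyParams(minFrac = 0.25))
  expect_identical(unclass(lab)[1], "A")
})

test_that("binning partitions reads and matches the origin manifest", {
  set.seed(25)
  p <- simParams(seed = 7, errorRate = 0.01, nBackground = 10,
                 coverage = 15)
  tx <- makeTranscriptome(p)
  org <- rand_dna(p$organelleLen)
  seqs <- c(as.character(tx$transcripts), organelle = org)
  sim <- simulateReads(seqs, p, seed = 70,
                       origins = c(names(tx$transcripts), "organelle"))
  idx <- buildKmerIndex(list(organelle = org), k = 31)
  outd <- tempfile()
  res <- splitReads(sim$reads1, sim$reads2, idx, classifyParams(), outd,
                    prefix = "s")
  # partition: summary counts sum to the input pair count
  expect_identical(sum(res$summary$count), length(sim$reads1))
  # concordance with ground truth
  truth <- ifelse(sim$manifest$origin == "organelle", "organelle",
                  "unclassified")
  expect_gte(mean(res$labels == truth), 0.99)
  # bins on disk are disjoint and exhaustive
  b1 <- readFastq(file.path(outd, "s_organelle_1.fastq.gz"))
  b2 <- readFastq(file.path(outd, "s_unclassified_1.fastq.gz"))
  expect_length(intersect(readIds(b1), readIds(b2)), 0)
  expect_setequal(c(readIds(b1), readIds(b2)), readIds(sim$reads1))
})

test_that("misassignment against the manifest stays below 1% at defaults", {
  set.seed(26)
  p <- simParams(seed = 8, errorRate = 0.01, nBackground = 20,
                 coverage = 20, organelleLen = 8000)
  tx <- makeTranscriptome(p)
  org <- rand_dna(8000)
  seqs <- c(as.character(tx$transcripts), organelle = org)
  sim <- simulateReads(seqs, p, seed = 80,
                       origins = c(names(tx$transcripts), "organelle"))
  n <- min(2000, length(sim$reads1))
  idx <- buildKmerIndex(list(organelle = org), k = 31)
  lab <- classifyReads(sim$reads1[1:n], sim$reads2[1:n], idx)
  truth <- ifelse(sim$manifest$origin[1:n] == "organelle", "organelle",
                  "unclassified")
  expect_gte(mean(unclass(lab) == truth), 0.99)
})
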