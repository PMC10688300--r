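test_that("k-mer counting matches a naive recount oracle", {
  expect_identical(sum(countKmers("ACGTACGT", 5)), 4L)
  # a read and its reverse complement count identically
  set.seed(51)
  r <- rand_dna(100)
  expect_identical(countKmers(r, 21), countKmers(revComp(r), 21))
  # brute-force recount on random reads (with Ns)
  reads <- vapply(rep(60, 100), function(n) {
    paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = "")
  }, character(1))
  got <- countKmers(reads, 15)
  want <- count_kmers_oracle(reads, 15)
  expect_identical(length(got), length(want))
  expect_identical(got[sort(names(got))],
                   setNames(as.integer(want[sort(names(got))]),
                            sort(names(got))))
  expect_error(countKmers("ACGT", 31), "exceeds")
})

test_that("graph construction filters by count and exposes branching", {
  set.seed(52)
  src <- rand_dna(500)
  reads <- substring(src, 1:(500 - 99), 100:500)
  counts <- countKmers(reads, 31)
  g <- buildGraph(counts, assemblyParams(minCount = 1))
  deg <- graphDegrees(g)
  # non-repetitive sequence: a single non-branching path
  expect_true(all(deg <= 1))
  expect_identical(sum(deg[, "in"] == 0), 1L)

  # min_count 2 removes singletons
  counts2 <- counts
  counts2[1] <- 1L
  g2 <- buildGraph(counts2, assemblyParams(minCount = 2))
  expect_false(names(counts2)[1] %in% g2@kmers)

  # an exact internal repeat >= k creates a branching node
  rep_unit <- rand_dna(40)
  src3 <- paste0(rand_dna(120), rep_unit, rand_dna(120), rep_unit,
                 rand_dna(120))
  reads3 <- substring(src3, 1:(nchar(src3) - 99), 100:nchar(src3))
  g3 <- buildGraph(countKmers(reads3, 31), assemblyParams(minCount = 1))
  expect_true(any(graphDegrees(g3) > 1))
})

test_that("tips from isolated sequencing errors are clipped", {
  set.seed(53)
  src <- rand_dna(400)
  clean <- substring(src, 1:(400 - 99), 100:400)
  clean <- rep(clean, 3)  # coverage ~3 per position path
  # one read with an error at its 3' end creates a short dead-end branch
  bad <- substr(src, 101, 200)
  substr(bad, 98, 98) <- if (substr(bad, 98, 98) == "A") "C" else "A"
  p <- assemblyParams(minCount = 1)
  g <- buildGraph(countKmers(c(clean, bad), 31), p)
  expect_gt(length(g@kmers), 400 - 31 + 1)   # error nodes present
  gc <- clipTips(g, p)
  expect_identical(length(gc@kmers), 400L - 31L + 1L)
  expect_setequal(gc@kmers, buildGraph(countKmers(clean, 31), p)@kmers)
  # clean graphs are a fixed point
  g2 <- buildGraph(countKmers(clean, 31), p)
  expect_identical(clipTips(g2, p)@kmers, g2@kmers)
})

test_that("heterozygous-SNP bubbles collapse onto the higher-coverage path", {
  set.seed(54)
  hap1 <- rand_dna(400)
  hap2 <- hap1
  substr(hap2, 200, 200) <- if (substr(hap1, 200, 200) == "G") "T" else "G"
  reads <- c(rep(substring(hap1, 1:(400 - 99), 100:400), 3),
             rep(substring(hap2, 1:(400 - 99), 100:400), 2))
  p <- assemblyParams(minCount = 1)
  g <- buildGraph(countKmers(reads, 31), p)
  gp <- popBubbles(g, p)
  contigs <- graphContigs(gp, p)
  expect_length(contigs, 1)
  expect_true(as.character(contigs[[1]]) %in%
                c(hap1, as.character(revComp(hap1))))
  # clean path graphs are unchanged
  g1 <- buildGraph(countKmers(substring(hap1, 1:(400 - 99), 100:400), 31), p)
  expect_identical(popBubbles(g1, p)@kmers, g1@kmers)
})

test_that("contig spelling, ordering and length arithmetic are exact", {
  set.seed(55)
  src <- rand_dna(200)  # 170 nodes at k=31 -> one 200-base contig
  reads <- substring(src, 1:(200 - 49), 50:200)
  p <- assemblyParams(minCount = 1, minContigLen = 200)
  contigs <- graphContigs(buildGraph(countKmers(reads, 31), p), p)
  expect_length(contigs, 1)
  expect_identical(width(contigs), 200L)
  expect_identical(names(contigs), "contig_1")
  expect_true(as.character(contigs[[1]]) %in%
                c(src, as.character(revComp(src))))
  # canonical orientation: the reported sequence is the lexicographic min
  expect_true(as.character(contigs[[1]]) <=
                as.character(revComp(as.character(contigs[[1]]))))
  # empty graph -> empty contig set
  empty <- buildGraph(setNames(integer(0), character(0)), p)
  expect_length(graphContigs(empty, p), 0)
})

test_that("planted transcripts are recovered exactly from tiling reads", {
  set.seed(56)
  tx <- rand_dna(1000)
  starts <- seq(1, 1000 - 99, by = 10)
  reads <- substring(tx, starts, starts + 99)
  p <- assemblyParams(minCount = 1)
  contigs <- assembleTargeted(reads, p)
  expect_length(contigs, 1)
  expect_true(as.character(contigs[[1]]) %in%
                c(tx, as.character(revComp(tx))))
  # determinism: byte-identical output on rerun
  again <- assembleTargeted(reads, p)
  expect_identical(as.character(contigs), as.character(again))
  # every contig k-mer exists in the input counts at >= minCount
  counts <- countKmers(reads, p$k)
  ck <- countKmers(as.character(contigs), p$k)
  expect_true(all(names(ck) %in% names(counts)))
  expect_true(all(counts[names(ck)] >= p$minCount))
  # empty input -> empty output
  expect_length(assembleTargeted(character(0), p), 0)
})

test_that("error-bearing reads at 30x still yield a near-exact transcript", {
  set.seed(13)
  p <- simParams(seed = 13, nBackground = 0, errorRate = 0.01,
                 coverage = 30)
  tx <- makeTranscriptome(p)
  target <- tx$truth$targetSeq
  sim <- simulateReads(c(target = target), p, seed = 130)
  contigs <- assembleTargeted(c(readSeqs(sim$reads1),
                                readSeqs(sim$reads2)),
                              assemblyParams())
  expect_gte(length(contigs), 1)
  best <- as.character(contigs[[1]])
  al <- pairwiseAlignment(DNAString(best), DNAString(target),
                          type = "local")
  al2 <- pairwiseAlignment(reverseComplement(DNAString(best)),
                           DNAString(target), type = "local")
  use <- if (score(al2) > score(al)) al2 else al
  alen <- nchar(as.character(pattern(use)))
  expect_gte(nmatch(use) / alen, 0.99)
  expect_gte(alen / nchar(target), 0.95)
})
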