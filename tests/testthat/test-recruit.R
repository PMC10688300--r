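test_that("query word indexing enumerates exact words with occurrences", {
  idx <- indexQueries(c(q1 = "MKTAYIAK"), seedParams(aaWord = 4))
  expect_length(idx, 5)
  expect_true(all(c("MKTA", "YIAK") %in% names(idx)))
  idx2 <- indexQueries(c(a = "MKTA", b = "MKTA"), seedParams(aaWord = 4))
  expect_identical(nrow(idx2[["MKTA"]]), 2L)
  expect_warning(indexQueries(c(tiny = "MK"), seedParams(aaWord = 4)),
                 "shorter than the word")
})

test_that("read scoring reflects translated homology", {
  set.seed(41)
  q <- rand_aa(300)
  # read whose +0 frame contains a verbatim 15-aa block of the query
  block <- substr(q, 101, 115)
  b62 <- scoringScheme()@matrix
  diag_sum <- sum(vapply(strsplit(block, "")[[1]],
                         function(a) b62[a, a], numeric(1)))
  read <- paste0(rand_dna(10), backtranslate(block), rand_dna(10))
  sc <- scoreReads(read, c(q = q))
  expect_gte(sc, diag_sum)
  # no word hits -> 0 (poly-A read against a query without K runs)
  expect_identical(scoreReads(strrep("C", 60), c(q = "MKTAYIAW")), 0L)
})

test_that("random reads rarely reach the recruitment threshold", {
  set.seed(11)
  q <- rand_aa(300)
  reads <- vapply(rep(150, 1000), rand_dna, character(1))
  sc <- scoreReads(reads, c(q = q))
  expect_gte(mean(sc < 50), 0.99)
})

test_that("stage-1 recruitment finds planted pairs with little background", {
  set.seed(5)
  p <- simParams(seed = 5, errorRate = 0.01)
  tx <- makeTranscriptome(p)
  sim <- simulateReads(tx$transcripts, p, seed = 50)
  tgt_ids <- sim$manifest$id[sim$manifest$origin == "target"][1:40]
  bg_ids <- sim$manifest$id[sim$manifest$origin != "target"][1:2000]
  sel <- which(readIds(sim$reads1) %in% c(tgt_ids, bg_ids))
  r1 <- sim$reads1[sel]; r2 <- sim$reads2[sel]
  queries <- c(target = tx$truth$protein)
  rec <- recruitSeed(r1, r2, queries)
  recall <- mean(tgt_ids %in% recruitedIds(rec))
  fp <- mean(bg_ids %in% recruitedIds(rec))
  expect_gte(recall, 0.95)
  expect_lte(fp, 0.01)
  expect_true(all(provenance(rec) == "seed"))
  # the recruited set is biased toward query similarity
  sc <- scoreReads(r1, queries)
  in_set <- readIds(r1) %in% recruitedIds(rec)
  expect_gt(mean(sc[in_set]), mean(sc[!in_set]))
})

test_that("threshold degeneracy and unique-id rules hold", {
  set.seed(43)
  q <- c(q = rand_aa(100))
  reads <- NucReads(sprintf("r%d", 1:50),
                    vapply(rep(120, 50), rand_dna, character(1)))
  sc <- scoreReads(reads, q)
  rec0 <- recruitSeed(reads, NULL, q, seedParams(minScore = 0))
  expect_setequal(recruitedIds(rec0), readIds(reads)[sc > 0])
  # monotonicity: lower thresholds never shrink recruitment
  sizes <- vapply(c(60, 30, 0), function(ms) {
    length(recruitSeed(reads, NULL, q,
                       seedParams(minScore = ms))@reads1)
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
  # duplicate ids are stored once
  dup <- c(reads, reads[1])
  recd <- recruitSeed(dup, NULL, q, seedParams(minScore = 0))
  expect_false(anyDuplicated(recruitedIds(recd)) > 0)
  expect_error(recruitSeed(reads, NULL, character(0)), "empty query set")
})

test_that("enrichment pulls in overlapping reads and extends recall", {
  # constructed overlap: a recruited read and a neighbor sharing 26+ bases
  set.seed(9)
  p <- simParams(seed = 9, errorRate = 0)
  tx <- makeTranscriptome(p)
  sim <- simulateReads(tx$transcripts, p, seed = 90)
  # queries = conserved core only (the middle third of the protein):
  # stage 1 sees only core-overlapping reads, enrichment reaches toward
  # the UTRs
  prot <- tx$truth$protein
  core <- substr(prot, 101, 200)
  stage1 <- recruitSeed(sim$reads1, sim$reads2, c(core = core))
  rec <- enrichReads(sim$reads1, sim$reads2, stage1)
  tgt <- sim$manifest$id[sim$manifest$origin == "target"]
  recall1 <- mean(tgt %in% recruitedIds(stage1))
  recall2 <- mean(tgt %in% recruitedIds(rec))
  expect_gt(recall2, recall1)
  expect_true(all(recruitedIds(stage1) %in% recruitedIds(rec)))
  expect_false(anyDuplicated(recruitedIds(rec)) > 0)
  expect_setequal(unique(provenance(rec)), c("seed", "enrich"))

  # empty stage 1 stays empty
  empty <- recruitSeed(sim$reads1[0], NULL, c(core = core))
  expect_length(enrichReads(sim$reads1, sim$reads2, empty)@reads1, 0)
})

test_that("a read overlapping a recruited read by nt_k+min_shared-1 bases is enriched", {
  set.seed(44)
  src <- rand_dna(400)
  seed_read <- NucReads("seed", substr(src, 101, 250))
  over <- NucReads("ovl", substr(src, 225, 374))  # 26-base overlap
  far <- NucReads("far", rand_dna(150))
  stage1 <- new("RecruitedReads", reads1 = seed_read, reads2 = NULL,
                provenance = c(seed = "seed"))
  rec <- enrichReads(c(seed_read, over, far), NULL, stage1,
                     enrichParams(ntK = 25, minShared = 2))
  expect_setequal(recruitedIds(rec), c("seed", "ovl"))
})
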