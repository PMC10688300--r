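test_that("FASTA reading handles multi-line records, descriptions and malformed input", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a some description", "AC", "GT", ">b", "T"), f)
  x <- readFasta(f, "DNA")
  expect_identical(names(x), c("a", "b"))
  expect_identical(as.character(x), c(a = "ACGT", b = "T"))
  expect_identical(S4Vectors::mcols(x)$description, c("some description", ""))

  writeLines(c(">only", "ACGT"), f)
  expect_identical(as.character(readFasta(f, "DNA")), c(only = "ACGT"))

  writeLines("ACGT", f)
  expect_error(readFasta(f, "DNA"), "line 1")
  expect_error(readFasta(tempfile(), "DNA"), "no such file")
})

test_that("FASTQ parsing decodes Phred+33, strips mate tags, rejects malformed records", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1/1", "ACGT", "+", "IIII",
               "@r2 2:N:0:ACGT", "ACGTN", "+", "II#!I"), f)
  x <- readFastq(f)
  expect_identical(readIds(x), c("r1", "r2"))
  expect_identical(qualInts(x)[[1]], rep(40L, 4))
  expect_identical(readMates(x), c(1L, 2L))

  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(readFastq(f), "different length")
})

test_that("FASTQ write/read round-trips records exactly, including gzip", {
  set.seed(101)
  n <- 100
  seqs <- vapply(sample(30:80, n, TRUE), rand_dna, character(1))
  quals <- vapply(nchar(seqs),
                  function(k) intToUtf8(sample(35:74, k, TRUE)),
                  character(1))
  reads <- NucReads(sprintf("read%03d", 1:n), seqs, quals)
  f <- tempfile(fileext = ".fastq.gz")
  writeFastq(reads, f)
  back <- readFastq(f)
  expect_identical(readIds(back), readIds(reads))
  expect_identical(unname(readSeqs(back)), unname(readSeqs(reads)))
  expect_identical(readQuals(back), readQuals(reads))
})

test_that("revComp is an involution, length preserving, N self-complementary", {
  expect_identical(revComp("ACGT"), "ACGT")
  expect_identical(revComp("AAC"), "GTT")
  expect_identical(revComp("ANT"), "ANT")
  expect_error(revComp("ACGU"), "invalid letter")
  set.seed(7)
  seqs <- vapply(sample(1:200, 1000, TRUE), function(n) {
    paste(sample(c("A", "C", "G", "T", "N"), n, TRUE), collapse = "")
  }, character(1))
  rc <- revComp(seqs)
  expect_identical(nchar(rc), nchar(seqs))
  expect_identical(revComp(rc), seqs)
})

test_that("translation follows the table, N codons give X, partial codons drop", {
  expect_identical(translateSeq("ATGAAATAG"), "MK*")
  expect_identical(translateSeq("AGA", geneticCode(2)), "*")
  expect_identical(translateSeq("ATGNA"), "M")
  expect_identical(translateSeq("ATGNAA"), "MX")
  expect_identical(translateSeq("ATGAAATAG", frame = 1), "*N")
  expect_error(translateSeq(""), "empty")
  expect_identical(nchar(translateSeq("ACGTACGTAC", frame = 2)),
                   (10L - 2L) %/% 3L)
})

test_that("six-frame translation covers both strands in fixed order", {
  sf <- sixFrame("ATGAAA")
  expect_identical(sf$strand, rep(c("+", "-"), each = 3))
  expect_identical(sf$frame, rep(0:2, 2))
  expect_identical(sf$aa[1], "MK")
  # reverse-strand frame 0 equals translate(revcomp)
  sf2 <- sixFrame("TTTCAT")
  expect_identical(sf2$aa[4], translateSeq(revComp("TTTCAT")))
  expect_identical(sf2$aa[4], "MK")
  sf3 <- sixFrame("ATG")
  expect_identical(nchar(sf3$aa), c(1L, 0L, 0L, 1L, 0L, 0L))
})

test_that("embedded genetic-code tables match the reference tables codon by codon", {
  for (id in geneticCodeIds()) {
    ref <- getGeneticCode(as.character(id), full.search = TRUE,
                          as.data.frame = TRUE)
    gc <- geneticCode(id)
    expect_identical(unname(gc@codonToAa[rownames(ref)]), ref$AA,
                     info = paste("table", id))
    expect_setequal(gc@startCodons, rownames(ref)[ref$Start != "-"])
  }
  expect_error(geneticCode(99), "unknown genetic-code table")
})

test_that("smithWaterman reproduces known scores and empty alignments", {
  al <- smithWaterman("MKT", "MKT")
  expect_identical(alignmentScore(al), 15L)
  expect_identical(al@identity, 1)
  expect_identical(al@qCov, 1)
  # no positive-scoring cell
  al0 <- smithWaterman("MKT", "PPPPPP")
  expect_identical(alignmentScore(al0), 0L)
  expect_identical(al0@qEnd - al0@qStart, 0L)
  expect_error(smithWaterman("", "MKT"), "empty")
})

test_that("smithWaterman agrees with an independent DP oracle and is self-maximal", {
  set.seed(42)
  for (i in 1:60) {
    a <- rand_aa(sample(5:25, 1))
    b <- rand_aa(sample(5:25, 1))
    expect_equal(alignmentScore(smithWaterman(a, b)),
                 sw_oracle_score(a, b), info = paste(a, b))
  }
  for (i in 1:20) {
    a <- rand_aa(20)
    b <- rand_aa(20)
    expect_gte(alignmentScore(smithWaterman(a, a)),
               alignmentScore(smithWaterman(a, b)))
  }
})
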