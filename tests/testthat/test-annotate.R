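strategy0 <- function(...) searchStrategy("test", character(0),
                                          orfMinLen = 1L, ...)

test_that("genomic sources map to their genetic codes", {
  expect_identical(geneticCodeFor("nucleus")@tableId, 1L)
  expect_identical(geneticCodeFor("plastid")@tableId, 11L)
  expect_identical(
    geneticCodeFor("mitochondrion",
                   sourceCodeMap(mitochondrion = 5))@tableId, 5L)
  expect_error(geneticCodeFor("apicoplast"), "unknown genomic source")
  expect_error(sourceCodeMap(nucleus = 3), "not among the embedded")
})

test_that("ORF finding handles the canonical worked example", {
  orfs <- findOrfs("AAATGAAATAGGG", "+", geneticCode(1), strategy0())
  comp <- orfs[orfs$completeness == "complete", ]
  expect_identical(nrow(comp), 1L)
  expect_identical(comp$start, 2L)
  expect_identical(comp$end, 11L)
  expect_identical(comp$aa, "MK")
  # no start codon, partials allowed: 5'-partial from the edge
  orfs2 <- findOrfs("AAACCCTAGGGG", "+", geneticCode(1), strategy0())
  expect_true("5prime_partial" %in% orfs2$completeness)
  p5 <- orfs2[orfs2$completeness == "5prime_partial", ][1, ]
  expect_identical(p5$start, 0L)
  # partials suppressed
  orfs3 <- findOrfs("AAACCCTAGGGG", "+", geneticCode(1),
                    searchStrategy("np", character(0), orfMinLen = 1,
                                   allowPartialOrfs = FALSE))
  expect_false("5prime_partial" %in% orfs3$completeness)
  # start codon without stop: 3'-partial
  orfs4 <- findOrfs("TAAATGAAAAAA", "+", geneticCode(1), strategy0())
  expect_true("3prime_partial" %in% orfs4$completeness)
})

test_that("ORF finding agrees with a brute-force enumerator on random contigs", {
  set.seed(61)
  s <- strategy0()
  code <- geneticCode(1)
  for (i in 1:300) {
    n <- sample(30:400, 1)
    contig <- paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                           prob = c(.245, .245, .245, .245, .02)),
                    collapse = "")
    strand <- sample(c("+", "-"), 1)
    got <- sort_orfs(findOrfs(contig, strand, code, s))
    want <- sort_orfs(orf_oracle(contig, strand, code@codonToAa,
                                 s@startCodons, 1, 100000))
    expect_identical(got, want, info = paste("contig", i, strand))
  }
})

test_that("ORF coordinates on the minus strand stay on the forward axis", {
  fwd <- "AAATGAAATAGGG"
  rc <- as.character(revComp(fwd))
  orfs <- findOrfs(rc, "-", geneticCode(1), strategy0())
  comp <- orfs[orfs$completeness == "complete", ]
  L <- nchar(rc)
  expect_identical(comp$start, L - 11L)
  expect_identical(comp$end, L - 2L)
  expect_identical(comp$aa, "MK")
  # extracting the forward slice and reverse-complementing translates
  # without internal stops
  nt <- revComp(substring(rc, comp$start + 1, comp$end))
  expect_identical(translateSeq(nt), "MK*")
})

test_that("transcript matching retains true matches and drops noise", {
  set.seed(62)
  prot <- rand_aa(120)
  s <- searchStrategy("m", character(0))
  contig <- paste0(rand_dna(30), backtranslate(prot), rand_dna(30))
  m <- matchTranscripts(c(ctg = contig), c(q = prot), s)
  expect_identical(nrow(m), 1L)
  expect_identical(m$strand, "+")
  expect_identical(m$identity, 1)
  expect_identical(m$qCov, 1)
  # minus-strand contig: same match, minus strand
  m2 <- matchTranscripts(c(ctg = as.character(revComp(contig))),
                         c(q = prot), s)
  expect_identical(m2$strand, "-")
  expect_identical(m2$identity, 1)
  # unrelated contigs almost never pass the thresholds
  hits <- 0L
  for (i in 1:100) {
    r <- matchTranscripts(c(x = rand_dna(500)), c(q = prot), s)
    hits <- hits + nrow(r)
  }
  expect_lte(hits, 1L)
})

test_that("CDS selection scores by query similarity with the tie cascade", {
  set.seed(63)
  prot <- paste0("M", rand_aa(79))
  cds <- backtranslate(prot)
  contig <- paste0("TAA", cds, rand_dna(40))
  s <- searchStrategy("sel", character(0), orfMinLen = 5)
  orfs <- findOrfs(contig, "+", geneticCode(1), s)
  pick <- selectCds(orfs, c(q = prot))
  expect_identical(pick$aa, prot)
  expect_identical(pick$completeness, "complete")
  # control mode: no queries, longest ORF wins on length score
  pick2 <- selectCds(orfs, NULL)
  expect_identical(pick2$score, max(nchar(orfs$aa)))
  # completeness breaks exact ties
  fake <- data.frame(start = c(10L, 0L), end = c(40L, 30L),
                     strand = "+", frame = 0L,
                     completeness = c("complete", "3prime_partial"),
                     aa = c(strrep("A", 10), strrep("A", 10)),
                     stringsAsFactors = FALSE)
  expect_identical(selectCds(fake, NULL)$completeness, "complete")
})

test_that("annotation outputs are valid and round-trip through GFF3", {
  set.seed(64)
  prot <- rand_aa(100)
  contig1 <- paste0(rand_dna(21), "TAA", backtranslate(prot), rand_dna(30))
  contig2 <- as.character(revComp(paste0(rand_dna(12), "TAA",
                                         backtranslate(prot),
                                         rand_dna(18))))
  contigs <- c(c1 = contig1, c2 = contig2)
  s <- searchStrategy("out", character(0), orfMinLen = 10)
  ann <- annotateContigs(contigs, c(q = prot), s)
  expect_identical(sort(ann$matches$contig), c("c1", "c2"))
  expect_identical(nrow(ann$cds), 2L)
  outd <- tempfile()
  files <- writeAnnotation(contigs, ann$matches, ann$cds, outd)
  expect_true(all(file.exists(files)))

  gff <- rtracklayer::import(files[["gff3"]])
  expect_identical(length(gff), 4L)  # 2 mRNA + 2 CDS
  cds_feats <- gff[gff$type == "CDS"]
  mrna <- gff[gff$type == "mRNA"]
  # 9-column structure round-trips with coordinates inside the contigs
  for (i in seq_along(cds_feats)) {
    cid <- as.character(GenomicRanges::seqnames(cds_feats))[i]
    expect_gte(GenomicRanges::start(cds_feats)[i], 1)
    expect_lte(GenomicRanges::end(cds_feats)[i], nchar(contigs[[cid]]))
    # CDS nested within its mRNA span
    m <- mrna[mrna$ID == unlist(cds_feats$Parent[i])]
    expect_gte(GenomicRanges::start(cds_feats)[i],
               GenomicRanges::start(m))
    expect_lte(GenomicRanges::end(cds_feats)[i], GenomicRanges::end(m))
  }
  expect_identical(unname(cds_feats$phase), c(0L, 0L))
  # 1-based conversion: plus-strand CDS starts one past the 0-based start
  c1row <- ann$cds[ann$cds$contig == "c1", ]
  g1 <- cds_feats[as.character(GenomicRanges::seqnames(cds_feats)) == "c1"]
  expect_identical(GenomicRanges::start(g1), c1row$start + 1L)
  expect_identical(GenomicRanges::end(g1), c1row$end)

  # every emitted CDS translates cleanly under its code
  nts <- readFasta(files[["orfs_nt"]], "DNA")
  aas <- readFasta(files[["orfs_aa"]], "AA")
  for (i in seq_along(nts)) {
    tr <- translateSeq(as.character(nts[[i]]))
    expect_false(grepl("\\*", sub("\\*$", "", tr)))
    expect_identical(sub("\\*$", "", tr), as.character(aas[[i]]))
  }
})
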