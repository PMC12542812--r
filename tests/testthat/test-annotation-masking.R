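test_that("GFF3 gene models convert coordinates and merge transcripts", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t300\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tx\texon\t1\t100\t.\t+\t.\tID=gA.e1;Parent=gA.t1",
    "chr1\tx\texon\t201\t300\t.\t+\t.\tID=gA.e2;Parent=gA.t1",
    "chr1\tx\tgene\t401\t490\t.\t+\t.\tID=gB",
    "chr1\tx\texon\t401\t490\t.\t+\t.\tID=gB.e1;Parent=gB",
    "chr1\tx\tgene\t501\t700\t.\t+\t.\tID=gC",
    "chr1\tx\tmRNA\t501\t700\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chr1\tx\tmRNA\t501\t700\t.\t+\t.\tID=gC.t2;Parent=gC",
    "chr1\tx\texon\t501\t600\t.\t+\t.\tID=gC.t1e;Parent=gC.t1",
    "chr1\tx\texon\t501\t620\t.\t+\t.\tID=gC.t2e;Parent=gC.t2"
  ), gff)
  gm <- parseGeneModels(gff)
  expect_named(gm, c("gA", "gB", "gC"))
  # two exons, genomic 1..100 and 201..300
  expect_equal(IRanges::start(gm$gA@exons), c(1L, 201L))
  expect_equal(IRanges::end(gm$gA@exons), c(100L, 300L))
  # single-exon gene: empty intron set downstream
  expect_length(subtractExons(gm$gB), 0L)
  # two transcripts with exons 1..100 and 1..120 merge to one 120-bp run
  expect_equal(length(gm$gC@exons), 1L)
  expect_equal(IRanges::width(gm$gC@exons), 120L)
})

test_that("exon outside its gene span is a validation error naming the gene", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t10\t100\t.\t+\t.\tID=gBad",
    "chr1\tx\texon\t5\t50\t.\t+\t.\tID=gBad.e1;Parent=gBad"
  ), gff)
  expect_error(parseGeneModels(gff), "gBad")
})

test_that("subtractExons returns the sorted gene-local complement", {
  gm <- GeneModel("g", "chr1", "+", IRanges::IRanges(1, 300),
                  IRanges::IRanges(c(1, 201), c(100, 300)))
  introns <- subtractExons(gm)
  expect_equal(IRanges::start(introns), 101L)
  expect_equal(IRanges::end(introns), 200L)

  gm2 <- GeneModel("g2", "chr1", "+", IRanges::IRanges(1, 500),
                   IRanges::IRanges(c(1, 101, 401), c(50, 150, 500)))
  i2 <- subtractExons(gm2)
  expect_equal(IRanges::start(i2), c(51L, 151L))
  expect_equal(IRanges::end(i2), c(100L, 400L))

  # full tiling -> empty
  gm3 <- GeneModel("g3", "chr1", "-", IRanges::IRanges(11, 100),
                   IRanges::IRanges(11, 100))
  expect_length(subtractExons(gm3), 0L)
})

test_that("exons and introns tile the gene and the order of exon input is
           irrelevant", {
  withr::with_seed(41, {
    for (i in 1:50) {
      gm <- randomGeneModel()
      introns <- subtractExons(gm)
      glen <- IRanges::width(gm@gene)
      covered <- sum(IRanges::width(gm@exons)) +
        sum(IRanges::width(introns))
      expect_equal(covered, glen)
      # permutation invariance of the exon input
      perm <- sample(seq_along(gm@exons))
      gm2 <- GeneModel(gm@geneId, gm@seqid, gm@strand, gm@gene,
                       gm@exons[perm])
      expect_equal(as.data.frame(subtractExons(gm2)),
                   as.data.frame(introns))
    }
  })
})

test_that("maskGene replaces intron positions and keeps exon characters", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  gm <- GeneModel("g", "chr1", "+", IRanges::IRanges(1, 10),
                  IRanges::IRanges(c(1, 7), c(4, 10)))
  mk <- maskGene(genome, gm)
  expect_equal(mk$sequence, "ACGT##GTAC")
  expect_equal(IRanges::start(mk$intronRuns), 5L)
  expect_equal(IRanges::end(mk$intronRuns), 6L)

  # no introns -> identity
  gm2 <- GeneModel("g2", "chr1", "+", IRanges::IRanges(1, 10),
                   IRanges::IRanges(1, 10))
  expect_equal(maskGene(genome, gm2)$sequence, "ACGTACGTAC")

  expect_error(maskGene(genome, GeneModel("g", "chrX", "+",
                                          IRanges::IRanges(1, 4),
                                          IRanges::IRanges(1, 4))),
               "chrX")
})

test_that("minus-strand masking commutes with reverse complementation", {
  withr::with_seed(42, {
    for (i in 1:20) {
      gm <- randomGeneModel()
      glen <- IRanges::width(gm@gene)
      contig <- paste(sample(c("A", "C", "G", "T"),
                             IRanges::end(gm@gene) + 10, replace = TRUE),
                      collapse = "")
      genome <- Biostrings::DNAStringSet(c(chr1 = contig))
      gmMinus <- GeneModel(gm@geneId, "chr1", "-", gm@gene, gm@exons)
      # oracle path: reverse-complement the raw gene subsequence first,
      # then mask the mirrored intron runs by hand
      sub <- substr(contig, IRanges::start(gm@gene), IRanges::end(gm@gene))
      rcChars <- strsplit(baitCarver:::revCompMasked(sub), "",
                          fixed = TRUE)[[1L]]
      runs <- bruteIntrons(gm)   # forward gene-local
      for (r in seq_along(runs)) {
        s <- glen - IRanges::end(runs)[r] + 1L
        e <- glen - IRanges::start(runs)[r] + 1L
        rcChars[s:e] <- "#"
      }
      viaOracle <- paste0(rcChars, collapse = "")
      viaMinus <- maskGene(genome, gmMinus)$sequence
      expect_equal(viaMinus, viaOracle)
      expect_equal(nchar(viaMinus), glen)
    }
  })
})

test_that("column annotation follows the reference row symbol by symbol", {
  aln <- LocusAlignment("loc", c(REF = "AC##-G", t1 = "ACGTAG"),
                        referenceRowId = "REF")
  ann <- annotateColumns(aln)
  expect_equal(ann@columnTrack,
               c("EXON", "EXON", "INTRON", "INTRON", "UNKNOWN", "EXON"))

  allNuc <- annotateColumns(LocusAlignment("l2", c(REF = "ACGT",
                                                   t1 = "ACGT"),
                                           referenceRowId = "REF"))
  expect_true(all(allNuc@columnTrack == "EXON"))

  allMask <- annotateColumns(LocusAlignment("l3", c(REF = "####",
                                                    t1 = "ACGT"),
                                            referenceRowId = "REF"))
  expect_true(all(allMask@columnTrack == "INTRON"))
  # degenerate: all-intron reference yields zero exon blocks
  expect_length(carve(allMask, findSplitRuns(allMask)), 0L)

  expect_error(annotateColumns(aln, "nope"), "nope")
})
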