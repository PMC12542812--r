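test_that("parsimony-informative sites follow the two-states-twice rule", {
  b <- exonBlockFromRows(c(a = "AAT", b = "AAT", c = "AAC", d = "AAC"))
  expect_equal(countPis(b), list(count = 1L, proportion = 1 / 3))

  same <- exonBlockFromRows(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_equal(countPis(same)$count, 0L)

  singletons <- exonBlockFromRows(c(a = "AT", b = "CT", c = "GT", d = "TT"))
  expect_equal(countPis(singletons)$count, 0L)

  # gaps and N never contribute a state: only the first column (A/A/C/C)
  # is informative, the gap/N column is not despite its 2+2 pattern
  gapped <- exonBlockFromRows(c(a = "A-", b = "A-", c = "CN", d = "CN"))
  expect_equal(countPis(gapped)$count, 1L)

  expect_error(countPis(exonBlockFromRows(c(a = "ACGT"))), "2 rows")
})

test_that("gap ratio is gaps over length with the boundary retained", {
  expect_equal(gapRatio("A-T-"), 0.5)
  expect_equal(gapRatio("----A"), 0.8)
  expect_equal(gapRatio("ACGT"), 0)
  expect_error(gapRatio(""), "empty")
})

test_that("mean pairwise identity excludes pair-gapped columns", {
  two <- exonBlockFromRows(c(a = "ACGT", b = "ACGT"))
  expect_equal(meanPairwiseIdentity(two), 100)
  boundary <- exonBlockFromRows(c(a = "AAAA", b = "AAAT"))
  expect_equal(meanPairwiseIdentity(boundary), 75)
  three <- exonBlockFromRows(c(a = "AAAA", b = "AAAT", c = "AATT"))
  expect_equal(meanPairwiseIdentity(three), mean(c(75, 50, 75)),
               tolerance = 1e-12)
  # a column gapped in one member of a pair is not compared for that pair
  gapped <- exonBlockFromRows(c(a = "A-GT", b = "ACGT"))
  expect_equal(meanPairwiseIdentity(gapped), 100)
  expect_error(meanPairwiseIdentity(
    exonBlockFromRows(c(a = "--A", b = "A--"))), "compared columns")
})

test_that("statistics agree with brute-force oracles on random alignments", {
  withr::with_seed(20, {
    for (rep in 1:60) {
      m <- randomAlnMatrix()
      expect_equal(countPis(m)$count, brutePis(m)$count)
      for (r in seq_len(nrow(m)))
        expect_equal(gapRatio(paste0(m[r, ], collapse = "")),
                     sum(m[r, ] == "-") / ncol(m))
      idOracle <- tryCatch(bruteIdentity(m), warning = function(w) NA)
      if (!is.na(idOracle))
        expect_equal(meanPairwiseIdentity(m), idOracle, tolerance = 1e-9)
    }
  })
})

test_that("stop-codon screen searches all three frames", {
  # clean coding rows in frame 0
  clean <- exonBlockFromRows(c(a = "ATGAAACCCGGG", b = "ATGAAACCCGGG"))
  expect_false(screenStopCodons(clean))

  # TAAA repeats carry an internal stop in every frame, so no frame
  # choice can rescue the block
  stopRow <- "TAAATAAATAAATAA"
  stopifnot(all(vapply(0:2, function(f) baitCarver:::internalStops(
    strsplit(stopRow, "")[[1]], f), integer(1L)) > 0L))
  forced <- exonBlockFromRows(c(a = stopRow, b = "ATGAAACCCGGGTTT"))
  expect_true(screenStopCodons(forced))

  # frame-1 coding fixture: prefix one base so frame 1 is stop-free while
  # frames 0 and 2 contain stops
  core <- "ATGAAACCCGGGTTT"
  shifted <- paste0("T", core)         # frame 1 reads `core`
  stopifnot(baitCarver:::internalStops(
    strsplit(shifted, "")[[1]], 1L) == 0L)
  b <- exonBlockFromRows(c(a = shifted, b = shifted))
  counts <- vapply(0:2, function(f)
    baitCarver:::internalStops(strsplit(shifted, "")[[1]], f), integer(1L))
  expect_equal(screenStopCodons(b), counts[2] > 0)
  expect_false(screenStopCodons(b))
})

test_that("gap-ratio stage removes rows and the block is re-evaluated", {
  base <- strrep("ACGTACGTAC", 81)            # 810 columns
  mut <- paste0(substr(base, 1, 800), "TTTTTTTTTT")
  rows <- c(setNames(rep(c(base, mut), 5), paste0("t", 1:10)))
  # one extra row that is 60% gaps
  gappy <- paste0(strrep("-", 486), substr(base, 487, 810))
  stopifnot(gapRatio(gappy) > 0.5)
  cladeMap <- setNames(rep(c("clade1", "clade2"), 6), paste0("t", 1:12))

  thr <- designThresholds(minPisFraction = 0, maxMeanGapRatio = 1)
  # 11 rows incl. the gappy one -> row removed -> 10 remain -> passes
  b11 <- exonBlockFromRows(c(rows, t11 = gappy))
  res11 <- applyCascade(list(b11), thr, cladeMap)
  expect_length(res11$survivors, 1L)
  expect_equal(length(res11$survivors[[1]]@aln), 10L)
  led <- res11$ledger
  expect_true(any(led$stage == "gap_ratio" & led$verdict == "row_removed"))

  # 10 rows incl. the gappy one -> 9 remain -> fails min_sequences
  b10 <- exonBlockFromRows(c(rows[1:9], t11 = gappy))
  res10 <- applyCascade(list(b10), thr, cladeMap)
  expect_length(res10$survivors, 0L)
  l10 <- res10$ledger
  expect_equal(l10$verdict[l10$stage == "min_sequences"], "fail")
  # rejected at min_sequences: no later-stage entries
  expect_false(any(l10$stage %in% c("pairwise_identity", "stop_codons",
                                    "clade_coverage")))
})

test_that("cascade order and monotonicity hold and input order is
           irrelevant", {
  spec <- fixtureSpec(nGenes = 10, nTaxa = 12)
  fx <- simGenome(spec, seed = 9, dir = tempfile())
  al <- simOrthologAlignments(spec, fx, seed = 9)
  blocks <- carveAll(al$alignments)
  thr <- designThresholds(minSequences = 8)
  res <- applyCascade(blocks, thr, spec$cladeMap)
  stages <- c("length_pass1", "pis", "length_pass2", "min_sequences",
              "pairwise_identity", "stop_codons", "mean_gap_ratio",
              "clade_coverage")
  led <- res$ledger
  # survivors of stage k+1 are a subset of survivors of stage k
  passed <- lapply(stages, function(s)
    led$locus[led$stage == s & led$verdict == "pass"])
  for (k in seq_len(length(stages) - 1L)) {
    expect_true(all(passed[[k + 1L]] %in% passed[[k]]))
  }
  # reordering the blocks leaves the outcome unchanged
  res2 <- applyCascade(rev(blocks), thr, spec$cladeMap)
  expect_equal(vapply(res2$survivors, blockId, character(1L)),
               vapply(res$survivors, blockId, character(1L)))
  expect_equal(res2$ledger, res$ledger)
})

test_that("a taxon missing from the clade map is a configuration error", {
  b <- exonBlockFromRows(c(x1 = "ACGT", x2 = "ACGT"))
  expect_error(applyCascade(list(b), designThresholds(),
                            c(x1 = "clade1")), "x2")
})
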