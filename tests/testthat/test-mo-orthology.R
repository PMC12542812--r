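test_that("support collapse contracts strictly-below-threshold branches", {
  tr <- ape::read.tree(text = "(((a,b)69,(c,d)70)100,e);")
  out <- collapseLowSupport(tr, threshold = 70)
  # (a,b) at 69 dissolves; (c,d) at 70 is retained
  cl <- baitCarver:::asTreeNode(out)
  labs <- lapply(cl$children, baitCarver:::nodeTips)
  expect_true(any(vapply(labs, function(x) setequal(x, c("c", "d")) ||
                           setequal(x, c("a", "b", "c", "d")),
                         logical(1L))))
  expect_setequal(out$tip.label, tr$tip.label)
  expect_equal(out$Nnode, tr$Nnode - 1L)

  # fully supported tree is unchanged
  strong <- ape::read.tree(text = "((a,b)100,(c,d)100);")
  expect_equal(ape::write.tree(collapseLowSupport(strong)),
               ape::write.tree(strong))

  # unlabeled branches are never collapsed
  plain <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(collapseLowSupport(plain)$Nnode, plain$Nnode)
})

test_that("a chain of weak branches collapses into one polytomy,
           independent of contraction order", {
  tr <- ape::read.tree(text = "((((a,b)50,c)60,d)40,(e,f)90);")
  out <- collapseLowSupport(tr, threshold = 70)
  # weak chain 50/60/40 all contract into the root; (e,f) survives
  expect_equal(out$Nnode, 2L)
  node <- baitCarver:::asTreeNode(out)
  expect_equal(length(node$children), 5L)   # a,b,c,d,(e,f)

  # oracle: contract the weak edges one at a time in every order
  weak <- c(50, 60, 40)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    tmp <- tr
    for (w in weak[p]) {
      tmp <- collapseLowSupport(tmp, threshold = w + 1)
    }
    expect_equal(tmp$Nnode, out$Nnode)
    expect_true(ape::all.equal.phylo(tmp, out, use.edge.length = FALSE))
  }
})

test_that("same-taxon tip masking keeps the longest sequence", {
  lens <- c("1" = 500, "2" = 300, "3" = 400, "4" = 500)
  cherry <- ape::read.tree(text = "((A@1,A@2),B@1);")
  out <- maskSameTaxonTips(cherry, lens)
  expect_setequal(out$tip.label, c("A@1", "B@1"))

  # ties break towards the smaller sequence id
  tie <- ape::read.tree(text = "((A@4,A@1),B@1);")
  expect_true("A@1" %in% maskSameTaxonTips(tie, lens)$tip.label)

  # no same-taxon neighbours: unchanged
  clean <- ape::read.tree(text = "((A@1,B@1),(C@1,D@1));")
  expect_setequal(maskSameTaxonTips(clean, lens)$tip.label,
                  clean$tip.label)

  # paraphyletic ladder keeps exactly one A tip (the longest)
  ladder <- ape::read.tree(text = "(A@1,(A@2,(A@3,B@1)));")
  out2 <- maskSameTaxonTips(ladder, lens)
  expect_setequal(out2$tip.label, c("A@1", "B@1"))

  expect_error(maskSameTaxonTips(cherry, c("2" = 10)), "A@1")
})

test_that("MO pruning keeps the larger duplication child and respects the
           ingroup minimum", {
  tr <- ape::read.tree(text = "(O@1,((A@1,(B@1,C@1)),(A@2,B@2)));")
  out <- moPrune(tr, ingroup = c("A", "B", "C"), outgroup = "O",
                 minIngroup = 2)
  expect_setequal(out$tip.label, c("O@1", "A@1", "B@1", "C@1"))

  # one-tip-per-taxon tree passes through (same taxa, no pruning)
  single <- ape::read.tree(text = "(O@1,((A@1,B@1),(C@1,D@1)));")
  out2 <- moPrune(single, ingroup = c("A", "B", "C", "D"), outgroup = "O",
                  minIngroup = 2)
  expect_setequal(out2$tip.label, single$tip.label)

  # ingroup minimum: 3 surviving ingroup taxa under minIngroup 4 -> none
  expect_null(moPrune(tr, ingroup = c("A", "B", "C"), outgroup = "O",
                      minIngroup = 4))

  # rejection reasons
  noOg <- ape::read.tree(text = "((A@1,B@1),(C@1,D@1));")
  log <- moPruneAll(list(a = noOg), ingroup = c("A", "B", "C", "D"),
                    outgroup = "O", minIngroup = 2)$log
  expect_equal(log$reason, "no_outgroup")

  repOg <- ape::read.tree(text = "((O@1,O@2),(A@1,B@1));")
  log2 <- moPruneAll(list(a = repOg), ingroup = c("A", "B"),
                     outgroup = "O", minIngroup = 2)$log
  expect_equal(log2$reason, "repeated_outgroup")

  scattered <- ape::read.tree(text = "((O@1,A@1),(P@1,B@1));")
  log3 <- moPruneAll(list(a = scattered), ingroup = c("A", "B"),
                     outgroup = c("O", "P"), minIngroup = 1)$log
  expect_equal(log3$reason, "outgroup_not_monophyletic")
})

test_that("MO pruning never repeats a taxon and keeps the larger side on
           planted duplications", {
  withr::with_seed(99, {
    for (rep in 1:60) {
      fx <- plantDuplication(nTaxa = sample(5:10, 1L))
      out <- moPrune(fx$tree, ingroup = fx$taxa, outgroup = fx$outgroup,
                     minIngroup = 1)
      expect_false(is.null(out))
      taxa <- sub("@.*$", "", out$tip.label)
      expect_false(anyDuplicated(taxa) > 0)
      # copy 1 is complete, copy 2 lost tips: the full ingroup survives
      expect_setequal(setdiff(taxa, fx$outgroup), fx$taxa)
      # inside the duplicated clade every kept tip is the @1 copy
      kept <- out$tip.label[taxa %in% fx$dupClade]
      expect_true(all(grepl("@1$", kept)))
    }
  })
})

test_that("MO pruning is invariant to child-order rotation and leaves
           duplication-free trees intact", {
  withr::with_seed(123, {
    for (rep in 1:20) {
      taxa <- paste0("t", 1:7)
      base <- ape::rtree(7, tip.label = paste0(taxa, "@1"), br = NULL)
      full <- baitCarver:::asPhylo(baitCarver:::newNode(list(
        baitCarver:::newTip("OUT@1"), baitCarver:::asTreeNode(base))))
      out <- moPrune(full, ingroup = taxa, outgroup = "OUT",
                     minIngroup = 1)
      expect_setequal(out$tip.label, full$tip.label)
      expect_true(ape::all.equal.phylo(out, full,
                                       use.edge.length = FALSE))
      rot <- ape::rotateConstr(full, sample(full$tip.label))
      out2 <- moPrune(rot, ingroup = taxa, outgroup = "OUT",
                      minIngroup = 1)
      expect_true(ape::all.equal.phylo(out2, out,
                                       use.edge.length = FALSE))
    }
  })
})

test_that("column trimming removes strictly-above-threshold columns", {
  rows10 <- function(missPerCol) {
    m <- matrix("A", nrow = 10, ncol = length(missPerCol))
    for (j in seq_along(missPerCol)) {
      if (missPerCol[j] > 0) m[seq_len(missPerCol[j]), j] <- "-"
    }
    rownames(m) <- paste0("s", 1:10)
    setNames(apply(m, 1, paste0, collapse = ""), rownames(m))
  }
  aln <- rows10(c(8, 7, 0))   # 80%, 70%, 0% missing
  out <- trimMissingColumns(aln, 0.70)
  expect_equal(unname(nchar(out[1])), 2L)   # 70% kept, 80% removed

  # no missing data: identity
  clean <- rows10(c(0, 0))
  expect_equal(trimMissingColumns(clean, 0.70), clean)

  # all columns trimmed: empty output with a warning
  expect_warning(empty <- trimMissingColumns(rows10(c(10, 10)), 0.5),
                 "empty")
  expect_equal(unname(nchar(empty[1])), 0L)

  # random fixture equals the per-column oracle (N counts as missing)
  withr::with_seed(31, {
    for (rep in 1:30) {
      m <- randomAlnMatrix(gapProb = 0.4, nProb = 0.2)
      thr <- sample(c(0.3, 0.5, 0.7), 1L)
      got <- suppressWarnings(trimMissingColumns(
        setNames(apply(m, 1, paste0, collapse = ""), rownames(m)), thr))
      oracle <- bruteTrim(m, thr)
      expect_equal(unname(got),
                   unname(apply(oracle, 1, paste0, collapse = "")))
    }
  })
})
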