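# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the helpers themselves write to tempdirs.

# Random gene model on a notional contig, for interval-algebra checks.
randomGeneModel <- function(maxLen = 500) {
  glen <- sample(30:maxLen, 1L)
  gstart <- sample(1:50, 1L)
  k <- sample(1:5, 1L)
  cuts <- sort(sample(0:glen, 2L * k, replace = TRUE))
  starts <- unique(cuts[seq(1L, 2L * k, by = 2L)])
  ends <- cuts[seq(2L, 2L * k, by = 2L)][seq_along(starts)]
  ok <- ends > starts
  starts <- starts[ok]; ends <- ends[ok]
  if (!length(starts)) { starts <- 0L; ends <- glen }
  exons <- IRanges::reduce(IRanges::IRanges(gstart + starts,
                                            gstart + ends - 1L))
  GeneModel(paste0("g", sample.int(1e6, 1L)), "chr1",
            sample(c("+", "-"), 1L),
            IRanges::IRanges(gstart, gstart + glen - 1L), exons)
}

# Brute-force intron oracle: per-base coverage scan over the gene span.
bruteIntrons <- function(gm) {
  gs <- IRanges::start(gm@gene); ge <- IRanges::end(gm@gene)
  covered <- rep(FALSE, ge - gs + 1L)
  for (i in seq_along(gm@exons)) {
    covered[(IRanges::start(gm@exons)[i] - gs + 1L):
            (IRanges::end(gm@exons)[i] - gs + 1L)] <- TRUE
  }
  r <- rle(!covered)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(IRanges::IRanges())
  IRanges::IRanges(startIdx[keep], endIdx[keep])
}

# Random small alignment (character matrix) for statistic oracles.
randomAlnMatrix <- function(nrow = NULL, ncol = NULL, gapProb = 0.15,
                            nProb = 0.05) {
  if (is.null(nrow)) nrow <- sample(2:8, 1L)
  if (is.null(ncol)) ncol <- sample(6:40, 1L)
  m <- matrix(sample(c("A", "C", "G", "T"), nrow * ncol, replace = TRUE),
              nrow = nrow)
  mask <- matrix(stats::runif(nrow * ncol), nrow = nrow)
  m[mask < gapProb] <- "-"
  m[mask >= gapProb & mask < gapProb + nProb] <- "N"
  rownames(m) <- paste0("s", seq_len(nrow))
  m
}

# Naive per-column PIS oracle.
brutePis <- function(m) {
  n <- 0L
  for (j in seq_len(ncol(m))) {
    counts <- integer(0)
    for (s in c("A", "C", "G", "T")) counts <- c(counts, sum(m[, j] == s))
    if (sum(counts >= 2L) >= 2L) n <- n + 1L
  }
  list(count = n, proportion = n / ncol(m))
}

# Naive all-pairs identity oracle.
bruteIdentity <- function(m) {
  vals <- c()
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):nrow(m)) {
      num <- 0L; den <- 0L
      for (k in seq_len(ncol(m))) {
        if (m[i, k] != "-" && m[j, k] != "-") {
          den <- den + 1L
          if (m[i, k] == m[j, k]) num <- num + 1L
        }
      }
      if (den > 0L) vals <- c(vals, num / den)
    }
  }
  mean(vals) * 100
}

# Naive column-trim oracle.
bruteTrim <- function(m, maxMissing) {
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    miss <- sum(m[, j] == "-" | m[, j] == "N") / nrow(m)
    keep[j] <- miss <= maxMissing
  }
  m[, keep, drop = FALSE]
}

# Random ingroup tree (one tip per taxon, labels taxon@1) plus one planted
# duplication: a random clade is duplicated and `loss` random tips are
# dropped from the second copy, so the two sides differ in size.
plantDuplication <- function(nTaxa = 8, outgroup = "OUT") {
  taxa <- paste0("t", seq_len(nTaxa))
  base <- ape::rtree(nTaxa, tip.label = taxa, br = NULL)
  node <- baitCarver:::asTreeNode(base)
  # collect internal clades with >= 2 tips
  clades <- list()
  walk <- function(n) {
    if (baitCarver:::nodeIsTip(n)) return(invisible())
    clades[[length(clades) + 1L]] <<- baitCarver:::nodeTips(n)
    lapply(n$children, walk)
    invisible()
  }
  walk(node)
  pick <- clades[[sample.int(length(clades), 1L)]]
  dropTip <- function(n, label) {
    if (baitCarver:::nodeIsTip(n)) return(n)
    keep <- list()
    for (ch in n$children) {
      if (baitCarver:::nodeIsTip(ch) && identical(ch$label, label)) next
      keep[[length(keep) + 1L]] <- dropTip(ch, label)
    }
    n$children <- keep
    if (length(n$children) == 1L) return(n$children[[1L]])
    n
  }
  dup <- function(n) {
    if (setequal(baitCarver:::nodeTips(n), pick)) {
      a <- relab(n, "1"); b <- relab(n, "2")
      loss <- sample(seq_len(max(1L, length(pick) - 1L)), 1L)
      for (l in sample(pick, loss)) b <- dropTip(b, paste0(l, "@2"))
      if (baitCarver:::nodeIsTip(b) || length(b$children) > 0L)
        return(baitCarver:::newNode(list(a, b)))
      return(a)
    }
    if (!baitCarver:::nodeIsTip(n)) n$children <- lapply(n$children, dup)
    n
  }
  relab <- function(n, tag) {
    if (baitCarver:::nodeIsTip(n)) {
      n$label <- paste0(n$label, "@", tag)
      return(n)
    }
    n$children <- lapply(n$children, relab, tag = tag)
    n
  }
  planted <- dup(node)
  # label remaining single-copy tips and attach the outgroup at the root
  fin <- function(n) {
    if (baitCarver:::nodeIsTip(n)) {
      if (!grepl("@", n$label, fixed = TRUE))
        n$label <- paste0(n$label, "@1")
      return(n)
    }
    n$children <- lapply(n$children, fin)
    n
  }
  planted <- fin(planted)
  full <- baitCarver:::newNode(list(baitCarver:::newTip(
    paste0(outgroup, "@1")), planted))
  list(tree = baitCarver:::asPhylo(full), dupClade = pick,
       taxa = taxa, outgroup = outgroup)
}
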