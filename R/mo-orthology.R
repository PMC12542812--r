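#' Collapse low-support branches into polytomies
#'
#' Every internal branch whose support value is strictly below the
#' threshold is contracted, merging the node into its parent; unlabeled
#' branches are never collapsed and the tip set is unchanged. Supports on
#' collapsed branches are discarded.
#'
#' @param tree an [ape::phylo] with numeric internal-node labels (supports),
#'   or a Newick path/string readable by [ape::read.tree].
#' @param threshold collapse supports strictly below this value, default 70.
#' @return an [ape::phylo] with the weak branches contracted.
#' @examples
#' tr <- ape::read.tree(text = "((a,b)60,(c,d)95);")
#' collapseLowSupport(tr)  # (a,b) dissolves into the root polytomy
#' @export
collapseLowSupport <- function(tree, threshold = 70) {
  if (is.character(tree)) tree <- readTreeFlexible(tree)
  root <- asTreeNode(tree)
  collapse <- function(node) {
    if (nodeIsTip(node)) return(node)
    node$children <- lapply(node$children, collapse)
    out <- list()
    for (ch in node$children) {
      if (!nodeIsTip(ch) && !is.na(ch$support) && ch$support < threshold) {
        out <- c(out, ch$children)   # contract: lift grandchildren
      } else {
        out <- c(out, list(ch))
      }
    }
    node$children <- out
    node
  }
  asPhylo(collapse(root))
}

#' Mask redundant same-taxon tips of a gene tree
#'
#' Within monophyletic or paraphyletic groups of tips belonging to one
#' taxon, only the tip with the most unambiguous characters is kept (ties
#' broken towards the lexicographically smallest sequence id). Two pruning
#' rules are applied to a fixpoint: sister tips of the same taxon
#' (monophyly) and a tip whose parent's sister is a same-taxon tip
#' (paraphyly).
#'
#' @param tree an [ape::phylo] with `taxon@sequenceID` tips.
#' @param sequenceLengths named numeric vector `sequence id -> unambiguous
#'   character count` (names may be either the full tip label or the
#'   sequence-id part).
#' @return an [ape::phylo] with redundant tips removed.
#' @export
maskSameTaxonTips <- function(tree, sequenceLengths) {
  if (is.character(tree)) tree <- readTreeFlexible(tree)
  lenOf <- function(tipLabel) {
    if (tipLabel %in% names(sequenceLengths))
      return(sequenceLengths[[tipLabel]])
    sid <- sub("^.*@", "", tipLabel)
    if (sid %in% names(sequenceLengths))
      return(sequenceLengths[[sid]])
    stop("no sequence length for tip '", tipLabel, "'")
  }
  better <- function(a, b) {       # TRUE if tip label a should be kept
    la <- lenOf(a); lb <- lenOf(b)
    if (la != lb) return(la > lb)
    sub("^.*@", "", a) < sub("^.*@", "", b)
  }
  root <- asTreeNode(tree)

  repeat {
    changed <- FALSE
    # monophyletic: two tip children of one node with the same taxon
    prune <- function(node) {
      if (nodeIsTip(node)) return(node)
      node$children <- lapply(node$children, prune)
      tipIdx <- which(vapply(node$children, nodeIsTip, logical(1L)))
      if (length(tipIdx) >= 2L) {
        labs <- vapply(node$children[tipIdx], `[[`, "", "label")
        tax <- taxonOf(labs)
        drop <- integer()
        for (t in unique(tax[duplicated(tax)])) {
          grp <- tipIdx[tax == t]
          best <- grp[1L]
          for (g in grp[-1L]) {
            if (better(node$children[[g]]$label,
                       node$children[[best]]$label)) best <- g
          }
          drop <- c(drop, setdiff(grp, best))
        }
        if (length(drop)) {
          node$children <- node$children[-drop]
          changed <<- TRUE
        }
      }
      node
    }
    root <- spliceUnary(prune(root))

    # paraphyletic: a tip child whose sibling subtree has a tip child of
    # the same taxon at its own top level ("uncle" rule)
    para <- function(node) {
      if (nodeIsTip(node)) return(node)
      node$children <- lapply(node$children, para)
      kids <- node$children
      tipIdx <- which(vapply(kids, nodeIsTip, logical(1L)))
      intIdx <- setdiff(seq_along(kids), tipIdx)
      for (ti in tipIdx) {
        tl <- kids[[ti]]$label
        for (ii in intIdx) {
          subTips <- which(vapply(kids[[ii]]$children, nodeIsTip,
                                  logical(1L)))
          for (si in subTips) {
            sl <- kids[[ii]]$children[[si]]$label
            if (taxonOf(tl) == taxonOf(sl)) {
              if (better(tl, sl)) {
                kids[[ii]]$children <- kids[[ii]]$children[-si]
              } else {
                kids[[ti]] <- NULL   # marks for removal below
              }
              node$children <- Filter(Negate(is.null), kids)
              changed <<- TRUE
              return(spliceUnaryChildren(node))
            }
          }
        }
      }
      node
    }
    root <- spliceUnary(para(root))
    if (!changed) break
  }
  asPhylo(root)
}

# splice unary children of a node in place
spliceUnaryChildren <- function(node) {
  node$children <- lapply(node$children, function(ch) {
    if (!nodeIsTip(ch) && length(ch$children) == 1L) ch$children[[1L]]
    else ch
  })
  node
}

#' Monophyletic-outgroup (MO) ortholog pruning
#'
#' Requires non-repeating, monophyletic outgroup tips; the tree is rooted on
#' the outgroup clade and traversed from the root towards the tips. At every
#' node whose child subtrees share at least one taxon (a duplication node)
#' the child with fewer tips is discarded (ties: discard the child whose
#' sorted tip-label tuple is lexicographically greater). The resulting
#' one-tip-per-taxon tree is emitted only when it retains at least
#' `minIngroup` ingroup taxa.
#'
#' @param tree an [ape::phylo] with `taxon@sequenceID` tips.
#' @param ingroup,outgroup character vectors partitioning the taxa.
#' @param minIngroup minimum ingroup taxa in the emitted ortholog,
#'   default 15.
#' @return an [ape::phylo] ortholog tree, or `NULL` when the tree is
#'   rejected (no outgroup, repeated outgroup taxon, non-monophyletic
#'   outgroup) or retains too few ingroup taxa. Use [moPruneAll()] to get
#'   the rejection reason codes.
#' @export
moPrune <- function(tree, ingroup, outgroup, minIngroup = 15) {
  moPruneDetailed(tree, ingroup, outgroup, minIngroup)$tree
}

#' MO-prune a collection of trees, logging rejection reasons
#'
#' @param trees named list of [ape::phylo] objects or a directory of Newick
#'   files.
#' @inheritParams moPrune
#' @return list with `orthologs` (named list of pruned [ape::phylo]) and
#'   `log` (data.frame: gene, status, reason).
#' @export
moPruneAll <- function(trees, ingroup, outgroup, minIngroup = 15) {
  if (is.character(trees)) {
    files <- sort(list.files(trees, pattern = "\\.(tre|nwk|newick|txt)$",
                             full.names = TRUE))
    trees <- setNames(lapply(files, readTreeFlexible),
                      sub("\\.[^.]*$", "", basename(files)))
  }
  res <- lapply(trees, moPruneDetailed, ingroup = ingroup,
                outgroup = outgroup, minIngroup = minIngroup)
  log <- data.frame(
    gene = names(trees),
    status = vapply(res, function(r)
      if (is.null(r$tree)) "rejected" else "ortholog", character(1L)),
    reason = vapply(res, function(r)
      if (is.null(r$tree)) r$reason else "", character(1L)),
    stringsAsFactors = FALSE)
  orthologs <- Filter(Negate(is.null), lapply(res, `[[`, "tree"))
  list(orthologs = orthologs, log = log)
}

moPruneDetailed <- function(tree, ingroup, outgroup, minIngroup = 15) {
  if (is.character(tree)) tree <- readTreeFlexible(tree)
  reject <- function(reason) list(tree = NULL, reason = reason)
  tips <- tree$tip.label
  tipTaxa <- taxonOf(tips)
  ogTips <- tips[tipTaxa %in% outgroup]
  if (!length(ogTips)) return(reject("no_outgroup"))
  if (anyDuplicated(tipTaxa[tipTaxa %in% outgroup]))
    return(reject("repeated_outgroup"))
  if (length(ogTips) == length(tips)) return(reject("too_few_ingroup"))

  rooted <- if (length(ogTips) == length(tips) - 1L) {
    # rooting on "all but one tip" is degenerate; root on the single
    # ingroup tip's edge instead, which yields the same rooted topology
    tryCatch(ape::root(tree, outgroup = setdiff(tips, ogTips),
                       resolve.root = TRUE),
             error = function(e) NULL)
  } else {
    tryCatch(ape::root(tree, outgroup = ogTips, resolve.root = TRUE),
             error = function(e) NULL)
  }
  if (is.null(rooted)) return(reject("outgroup_not_monophyletic"))
  if (!ape::is.monophyletic(rooted, ogTips))
    return(reject("outgroup_not_monophyletic"))

  root <- asTreeNode(rooted)
  pruneDups <- function(node) {
    if (nodeIsTip(node)) return(node)
    repeat {
      if (length(node$children) < 2L) break
      taxaSets <- lapply(node$children, nodeTaxa)
      dropped <- FALSE
      for (i in seq_len(length(node$children) - 1L)) {
        for (j in (i + 1L):length(node$children)) {
          if (length(intersect(taxaSets[[i]], taxaSets[[j]])) > 0L) {
            ni <- nodeNtips(node$children[[i]])
            nj <- nodeNtips(node$children[[j]])
            drop <- if (ni != nj) {
              if (ni < nj) i else j
            } else {
              keyI <- paste(sort(nodeTips(node$children[[i]])),
                            collapse = "\r")
              keyJ <- paste(sort(nodeTips(node$children[[j]])),
                            collapse = "\r")
              if (keyI > keyJ) i else j
            }
            node$children <- node$children[-drop]
            dropped <- TRUE
            break
          }
        }
        if (dropped) break
      }
      if (!dropped) break
    }
    node$children <- lapply(node$children, pruneDups)
    if (length(node$children) == 1L) return(node$children[[1L]])
    node
  }
  pruned <- pruneDups(root)
  nIngroup <- length(intersect(nodeTaxa(pruned), ingroup))
  if (nIngroup < minIngroup) return(reject("too_few_ingroup"))
  list(tree = asPhylo(pruned), reason = "")
}

#' Trim alignment columns with excess missing data
#'
#' Columns whose fraction of missing characters (gap or `N`) is strictly
#' greater than `maxMissingFraction` are removed; row order is preserved.
#'
#' @param alignment named character vector of aligned rows, a
#'   [Biostrings::BStringSet], or a [LocusAlignment-class].
#' @param maxMissingFraction default 0.70.
#' @return object of the same flavour with the offending columns removed;
#'   an empty-alignment warning is raised when every column is trimmed.
#' @export
trimMissingColumns <- function(alignment, maxMissingFraction = 0.70) {
  isLocus <- methods::is(alignment, "LocusAlignment")
  seqs <- if (isLocus) alignment@seqs else alignment
  m <- alnMatrix(seqs)
  miss <- colSums(m == GAP_CHAR | m == "N") / nrow(m)
  keep <- miss <= maxMissingFraction
  if (!any(keep)) {
    warning("all columns trimmed: empty alignment returned")
    trimmed <- setNames(rep("", nrow(m)), rownames(m))
  } else {
    trimmed <- matrixAln(m[, keep, drop = FALSE])
  }
  if (isLocus) {
    alignment@seqs <- Biostrings::BStringSet(trimmed)
    alignment@columnTrack <- if (length(alignment@columnTrack))
      alignment@columnTrack[keep] else character()
    return(alignment)
  }
  if (methods::is(seqs, "XStringSet")) Biostrings::BStringSet(trimmed)
  else trimmed
}

# Read Newick from a path or a literal string; supports both the
# node-label and branch-comment support dialects (comments [n] after the
# closing parenthesis are rewritten into node labels before parsing).
readTreeFlexible <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x, warn = FALSE),
                                   collapse = "") else x
  txt <- gsub("\\)\\s*\\[([0-9.]+)\\]", ")\\1", txt)
  ape::read.tree(text = txt)
}
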