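# Recursive tree representation used by the tree-surgery operations.
# A node is list(label = chr or NA, support = num or NA, children = list()).
# Tips have an empty children list and a non-NA label. ape::phylo is the
# interchange format: ape parses/serialises Newick; surgery happens here.

#' @importFrom ape read.tree write.tree Ntip getMRCA is.rooted root
NULL

nodeIsTip <- function(node) length(node$children) == 0L

newTip <- function(label) list(label = label, support = NA_real_,
                               children = list())

newNode <- function(children, support = NA_real_) {
  list(label = NA_character_, support = support, children = children)
}

# Convert an ape phylo into the recursive representation. Internal node
# labels that parse as numbers become supports.
asTreeNode <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  nodeLab <- phy$node.label
  build <- function(i) {
    if (i <= ntip) return(newTip(phy$tip.label[i]))
    ch <- lapply(kids[[as.character(i)]], build)
    sup <- NA_real_
    if (!is.null(nodeLab)) {
      lab <- nodeLab[i - ntip]
      if (!is.na(lab) && nzchar(lab)) {
        v <- suppressWarnings(as.numeric(lab))
        if (!is.na(v)) sup <- v
      }
    }
    newNode(ch, support = sup)
  }
  build(ntip + 1L)
}

# Serialise a node back to Newick (supports as internal node labels).
nodeNewick <- function(node) {
  rec <- function(n) {
    if (nodeIsTip(n)) return(n$label)
    inner <- paste(vapply(n$children, rec, character(1L)), collapse = ",")
    sup <- if (!is.na(n$support)) format(n$support) else ""
    paste0("(", inner, ")", sup)
  }
  paste0(rec(node), ";")
}

asPhylo <- function(node) {
  ape::read.tree(text = nodeNewick(node))
}

nodeTips <- function(node) {
  if (nodeIsTip(node)) return(node$label)
  unlist(lapply(node$children, nodeTips))
}

# taxon prefix of taxon@sequenceID labels
taxonOf <- function(labels) sub("@.*$", "", labels)

nodeTaxa <- function(node) unique(taxonOf(nodeTips(node)))

nodeNtips <- function(node) length(nodeTips(node))

# Splice out unary nodes (a node with one child is replaced by the child).
spliceUnary <- function(node) {
  if (nodeIsTip(node)) return(node)
  node$children <- lapply(node$children, spliceUnary)
  if (length(node$children) == 1L) return(node$children[[1L]])
  node
}
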