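#' Extract rooted orthogroups from a homolog tree
#'
#' An orthogroup is a maximal rooted subtree whose tips are all ingroup and
#' that contains at least `minIngroup` distinct ingroup taxa. The tree is
#' consumed as rooted: the presence of at least one outgroup tip anywhere in
#' the tree vouches for the rooting (the upstream pipeline roots homolog
#' trees on their outgroups); a rooted all-ingroup tree is accepted whole,
#' while an unrooted tree without outgroup evidence is rejected.
#'
#' @param tree an [ape::phylo] homolog tree with `taxon@sequenceID` tips.
#' @param ingroup,outgroup taxon partition.
#' @param minIngroup minimum distinct ingroup taxa per orthogroup,
#'   default 10.
#' @return list of [ape::phylo] orthogroup subtrees (possibly empty), or
#'   `NULL` when the tree is unrooted and carries no outgroup evidence.
#' @export
extractOrthogroups <- function(tree, ingroup, outgroup, minIngroup = 10) {
  if (is.character(tree)) tree <- readTreeFlexible(tree)
  tipTaxa <- taxonOf(tree$tip.label)
  hasOutgroup <- any(tipTaxa %in% outgroup)
  if (!hasOutgroup && !ape::is.rooted(tree))
    return(NULL)
  root <- asTreeNode(tree)
  found <- list()
  walk <- function(node) {
    taxa <- nodeTaxa(node)
    if (all(taxa %in% ingroup)) {
      if (length(taxa) >= minIngroup)
        found[[length(found) + 1L]] <<- node
      return(invisible())
    }
    if (!nodeIsTip(node)) lapply(node$children, walk)
    invisible()
  }
  walk(root)
  lapply(found, asPhylo)
}

#' Map concordant duplications of an orthogroup onto the species tree
#'
#' A node of the orthogroup is a duplication when its two child subtrees
#' share at least one taxon. The duplication is concordant (and mapped) when
#' the species-tree MRCA of the left-child taxa equals the MRCA of the
#' right-child taxa; the duplication is assigned to that shared node's
#' subtending branch. Discordant duplications (unequal MRCAs, or
#' polytomous duplication nodes) are counted separately and not mapped.
#' Terminal branches can receive duplications (both MRCAs = the tip).
#'
#' @param orthogroup an [ape::phylo] whose tips are all ingroup.
#' @param speciesTree an [ape::phylo] with one tip per taxon.
#' @return list with `mapped` (character vector of branch ids: the sorted
#'   taxa of the species-tree clade under the branch, collapsed with
#'   `","`), `nDiscordant`, and `nDuplications`.
#' @export
mapDuplications <- function(orthogroup, speciesTree) {
  og <- asTreeNode(orthogroup)
  taxa <- nodeTaxa(og)
  absent <- setdiff(taxa, speciesTree$tip.label)
  if (length(absent))
    stop("taxa absent from the species tree: ",
         paste(absent, collapse = ", "))
  mapped <- character()
  nDisc <- 0L
  nDup <- 0L
  walk <- function(node) {
    if (nodeIsTip(node)) return(invisible())
    lapply(node$children, walk)
    taxaSets <- lapply(node$children, nodeTaxa)
    shared <- length(node$children) >= 2L &&
      anyDuplicated(unlist(taxaSets)) > 0L
    if (!shared) return(invisible())
    nDup <<- nDup + 1L
    if (length(node$children) != 2L) {
      nDisc <<- nDisc + 1L
      return(invisible())
    }
    mrcas <- vapply(taxaSets, speciesMrcaNode,
                    integer(1L), speciesTree = speciesTree)
    if (mrcas[1L] == mrcas[2L]) {
      mapped <<- c(mapped, speciesBranchId(speciesTree, mrcas[1L]))
    } else {
      nDisc <<- nDisc + 1L
    }
    invisible()
  }
  walk(og)
  list(mapped = mapped, nDiscordant = nDisc, nDuplications = nDup)
}

# species-tree node (ape index) that is the MRCA of a taxon set
speciesMrcaNode <- function(taxa, speciesTree) {
  idx <- match(taxa, speciesTree$tip.label)
  if (length(idx) == 1L) return(idx)
  as.integer(ape::getMRCA(speciesTree, idx))
}

# branch id = sorted taxa of the clade under the node, comma-collapsed
speciesBranchId <- function(speciesTree, node) {
  ntip <- length(speciesTree$tip.label)
  tips <- if (node <= ntip) speciesTree$tip.label[node] else {
    kids <- split(speciesTree$edge[, 2L], speciesTree$edge[, 1L])
    collect <- function(i) {
      if (i <= ntip) return(speciesTree$tip.label[i])
      unlist(lapply(kids[[as.character(i)]], collect))
    }
    collect(node)
  }
  paste(sort(tips), collapse = ",")
}

# all branch ids of a species tree (one per node: tips and internals)
speciesBranchIds <- function(speciesTree) {
  ntip <- length(speciesTree$tip.label)
  nnode <- speciesTree$Nnode
  vapply(seq_len(ntip + nnode), speciesBranchId, character(1L),
         speciesTree = speciesTree)
}

#' Per-branch duplication percentages across orthogroups
#'
#' For each species-tree branch: `n_duplications` counts orthogroups with
#' at least one duplication mapped there; `n_informative` counts
#' orthogroups able to witness a duplication on that branch (an internal
#' branch is witnessed when the orthogroup's taxa reach at least two
#' different child subtrees of the branch's node; a terminal branch when
#' the orthogroup contains that taxon); the percentage is
#' `100 * n_duplications / n_informative`, reported `NA` (undefined, not
#' zero) when no orthogroup is informative.
#'
#' @param orthogroups list of [ape::phylo] orthogroups.
#' @param speciesTree species tree ([ape::phylo]).
#' @return data.frame: branch (id), n_duplications, n_informative,
#'   percentage.
#' @export
branchPercentages <- function(orthogroups, speciesTree) {
  ids <- speciesBranchIds(speciesTree)
  ntip <- length(speciesTree$tip.label)
  kids <- split(speciesTree$edge[, 2L], speciesTree$edge[, 1L])
  cladeTaxa <- lapply(seq_along(ids), function(node) {
    strsplit(ids[node], ",", fixed = TRUE)[[1L]]
  })
  childTaxa <- lapply(seq_along(ids), function(node) {
    if (node <= ntip) return(NULL)
    lapply(kids[[as.character(node)]], function(ch)
      strsplit(speciesBranchId(speciesTree, ch), ",", fixed = TRUE)[[1L]])
  })

  nDup <- setNames(integer(length(ids)), ids)
  nInf <- setNames(integer(length(ids)), ids)
  for (og in orthogroups) {
    taxa <- unique(taxonOf(og$tip.label))
    res <- mapDuplications(og, speciesTree)
    hit <- unique(res$mapped)
    nDup[hit] <- nDup[hit] + 1L
    for (node in seq_along(ids)) {
      informative <- if (node <= ntip) {
        ids[node] %in% taxa
      } else {
        reached <- vapply(childTaxa[[node]], function(ct)
          any(ct %in% taxa), logical(1L))
        sum(reached) >= 2L
      }
      if (informative) nInf[node] <- nInf[node] + 1L
    }
  }
  data.frame(branch = ids, n_duplications = unname(nDup),
             n_informative = unname(nInf),
             percentage = ifelse(nInf > 0, 100 * nDup / nInf, NA_real_),
             stringsAsFactors = FALSE)
}
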