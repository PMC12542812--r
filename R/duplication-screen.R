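#' Taxon occurrence counts in a homolog gene tree
#'
#' Tip labels follow the `taxon@sequenceID` convention; the taxon prefix of
#' each tip is tallied.
#'
#' @param tree an [ape::phylo] homolog tree, or a path to a Newick file.
#' @return named integer vector `taxon -> tip count` (absent taxa have no
#'   entry).
#' @examples
#' tr <- ape::read.tree(text = "((A@1,A@2),B@1);")
#' countTaxonOccurrences(tr)  # A = 2, B = 1
#' @export
countTaxonOccurrences <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  tips <- tree$tip.label
  bad <- !grepl("@", tips, fixed = TRUE) |
    vapply(gregexpr("@", tips, fixed = TRUE),
           function(g) length(g) != 1L || g[1L] == -1L, logical(1L))
  if (any(bad))
    stop("tip label(s) without exactly one '@': ",
         paste(tips[bad], collapse = ", "))
  taxa <- sub("@.*$", "", tips)
  tab <- table(taxa)
  setNames(as.integer(tab), names(tab))
}

#' Build an occurrence table over a directory or list of homolog trees
#'
#' @param trees named list of [ape::phylo] objects (names = gene ids) or a
#'   directory of Newick files (file base name = gene id).
#' @return data.frame with columns `gene`, `taxon`, `count`.
#' @export
occurrenceTable <- function(trees) {
  if (is.character(trees)) {
    files <- sort(list.files(trees, pattern = "\\.(tre|nwk|newick|txt)$",
                             full.names = TRUE))
    trees <- setNames(lapply(files, ape::read.tree),
                      sub("\\.[^.]*$", "", basename(files)))
  }
  do.call(rbind, lapply(names(trees), function(g) {
    counts <- countTaxonOccurrences(trees[[g]])
    data.frame(gene = g, taxon = names(counts), count = unname(counts),
               stringsAsFactors = FALSE)
  }))
}

#' Remove loci with gene-family expansion in diploid reference taxa
#'
#' Duplications per taxon are counted as tip copies minus one (zero when the
#' taxon is absent). A locus is removed when the duplication count strictly
#' exceeds `maxDuplications` for any of the reference taxa ("either
#' species"): copy count 4 (three duplications) is kept, copy count 5 is
#' removed under the default ceiling of 3.
#'
#' @param loci character vector of locus ids.
#' @param locusGene named character vector `locus id -> gene id`.
#' @param occurrences data.frame from [occurrenceTable()].
#' @param referenceTaxa taxa known to lack a whole-genome duplication.
#' @param maxDuplications ceiling, default 3.
#' @param missingTree `"drop"` (default, conservative: a locus whose gene
#'   has no homolog tree offers no evidence of low copy number) or
#'   `"keep"`.
#' @return character vector of surviving locus ids (subset of `loci`,
#'   original order preserved).
#' @export
diploidDuplicationFilter <- function(loci, locusGene, occurrences,
                                     referenceTaxa, maxDuplications = 3,
                                     missingTree = c("drop", "keep")) {
  missingTree <- match.arg(missingTree)
  if (!length(referenceTaxa))
    stop("at least one diploid reference taxon is required")
  unknown <- setdiff(loci, names(locusGene))
  if (length(unknown))
    stop("loci without a gene mapping: ", paste(unknown, collapse = ", "))
  genesWithTree <- unique(occurrences$gene)
  keep <- vapply(loci, function(l) {
    g <- locusGene[[l]]
    if (!g %in% genesWithTree) return(missingTree == "keep")
    sub <- occurrences[occurrences$gene == g &
                         occurrences$taxon %in% referenceTaxa, , drop = FALSE]
    dups <- setNames(rep(0L, length(referenceTaxa)), referenceTaxa)
    if (nrow(sub)) dups[sub$taxon] <- sub$count - 1L
    all(dups <= maxDuplications)
  }, logical(1L))
  loci[keep]
}
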