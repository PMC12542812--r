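#' Run the full bait-design pipeline
#'
#' Carves exon blocks out of ortholog alignments that contain an
#' intron-masked reference row, applies the filtering cascade, removes loci
#' with gene-family expansion in the diploid reference taxa (when homolog
#' trees are supplied), draws the kit subset, selects per-clade
#' representatives and tiles the probes.
#'
#' @param alignments named list of [LocusAlignment-class] objects (names =
#'   ortholog/gene ids) or a directory of aligned FASTA files.
#' @param cladeMap named character vector `taxon -> clade`.
#' @param thresholds a [DesignThresholds-class].
#' @param seed integer seed driving the kit subset and representative
#'   draws.
#' @param referenceRowId masked reference row id (used when reading a
#'   directory), default `"REF_genome"`.
#' @param homologTrees optional named list of [ape::phylo] (names = gene
#'   ids) or tree directory for the duplication screen.
#' @param referenceTaxa diploid reference taxa for the duplication screen;
#'   required when `homologTrees` is given.
#' @param kitSize loci retained in the kit; `NULL` keeps all survivors.
#' @param outDir optional output directory (`filter_ledger.tsv`,
#'   `locus_stats.tsv`, `targets.fasta`, `probes.fasta`,
#'   `design_report.tsv`).
#' @return list with `blocks`, `survivors`, `ledger`, `postDuplication`
#'   (locus ids), `design` (result of [designBaits()]).
#' @export
runBaitPipeline <- function(alignments, cladeMap,
                            thresholds = designThresholds(), seed = 1L,
                            referenceRowId = "REF_genome",
                            homologTrees = NULL, referenceTaxa = NULL,
                            kitSize = NULL, outDir = NULL) {
  blocks <- carveAll(alignments, referenceRowId = referenceRowId)
  casc <- applyCascade(blocks, thresholds, cladeMap)
  survivors <- casc$survivors

  ids <- vapply(survivors, blockId, character(1L))
  locusGene <- setNames(vapply(survivors, function(b) b@orthologId,
                               character(1L)), ids)
  post <- ids
  if (!is.null(homologTrees)) {
    if (is.null(referenceTaxa))
      stop("referenceTaxa is required for the duplication screen")
    occ <- occurrenceTable(homologTrees)
    post <- diploidDuplicationFilter(ids, locusGene, occ, referenceTaxa,
                                     thresholds@maxDuplications)
  }
  kept <- survivors[match(post, ids)]

  design <- designBaits(kept, cladeMap, seed = seed, kitSize = kitSize,
                        probeLen = thresholds@probeLen,
                        tiling = thresholds@tiling, outDir = outDir,
                        locusGene = locusGene)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(casc$ledger,
                       file.path(outDir, "filter_ledger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stats <- locusStats(kept, cladeMap)
    utils::write.table(stats, file.path(outDir, "locus_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(blocks = blocks, survivors = survivors, ledger = casc$ledger,
       postDuplication = post, design = design)
}
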