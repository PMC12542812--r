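#' Pick one fewest-gap representative per clade for a locus
#'
#' Within each clade the candidate sequences are those with the minimal gap
#' count; one candidate is drawn uniformly from a per-locus random stream
#' derived by hashing `(seed, locus id)`, so the choice is deterministic
#' given the seed and independent of locus processing order.
#'
#' @param block an [ExonBlock-class].
#' @param cladeMap named character vector `taxon -> clade label`.
#' @param seed integer top-level design seed.
#' @param clades clade labels to represent; defaults to every clade present
#'   in `cladeMap`.
#' @return data.frame with one row per clade: locus, clade,
#'   representative_id, gap_count.
#' @export
selectRepresentatives <- function(block, cladeMap, seed,
                                  clades = sort(unique(unname(cladeMap)))) {
  m <- blockMatrix(block)
  gaps <- rowSums(m == GAP_CHAR)
  rowClade <- unname(cladeMap[rownames(m)])
  id <- blockId(block)
  out <- lapply(clades, function(cl) {
    members <- which(rowClade == cl)
    if (!length(members))
      stop("required clade '", cl, "' absent from locus '", id, "'")
    g <- gaps[members]
    cand <- sort(rownames(m)[members][g == min(g)])
    pick <- if (length(cand) == 1L) cand else {
      withSeed(substreamSeed(seed, paste0(id, "|", cl)),
               sample(cand, 1L))
    }
    data.frame(locus = id, clade = cl, representative_id = pick,
               gap_count = min(g), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Random kit-size subset of candidate loci
#'
#' Uniform sample without replacement under the given seed; the result is
#' returned in stable order (sorted by locus id).
#'
#' @param loci character vector of candidate locus ids.
#' @param kitSize number of loci to keep, default 1000.
#' @param seed integer seed.
#' @return sorted character vector of `kitSize` locus ids.
#' @export
subsetKit <- function(loci, kitSize = 1000, seed) {
  loci <- sort(unique(loci))
  if (length(loci) < kitSize)
    stop("kit size ", kitSize, " exceeds the ", length(loci),
         " candidate loci (shortfall ", kitSize - length(loci), ")")
  if (length(loci) == kitSize) return(loci)
  sort(withSeed(substreamSeed(seed, "kit_subset"),
                sample(loci, kitSize)))
}

#' Tile probes along an ungapped target sequence
#'
#' For a 2x tiling, probes start every `probeLen / tiling` bases; a
#' flush-end probe at `L - probeLen` is added when the last regular start
#' does not already reach the 3' end, so terminal bases are covered.
#'
#' @param sequence ungapped target sequence (character scalar).
#' @param probeLen probe length in nt, default 120.
#' @param tiling tiling factor, default 2 (step = probeLen / tiling).
#' @param dropN drop probes containing at least one `N`, default `TRUE`.
#' @return data.frame with columns `start` (0-based offset) and `probe`;
#'   attribute `n_dropped_N` counts N-containing probes removed.
#' @examples
#' tileProbes(paste(rep("ACGT", 75), collapse = ""))  # L = 300 -> 4 probes
#' @export
tileProbes <- function(sequence, probeLen = 120, tiling = 2, dropN = TRUE) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L < probeLen)
    stop("sequence length ", L, " is shorter than the probe length ",
         probeLen)
  step <- probeLen / tiling
  starts <- seq.int(0L, L - probeLen, by = step)
  if (starts[length(starts)] != L - probeLen)
    starts <- c(starts, L - probeLen)
  probes <- substring(sequence, starts + 1L, starts + probeLen)
  dropped <- 0L
  if (dropN) {
    hasN <- grepl("N", probes, fixed = TRUE)
    dropped <- sum(hasN)
    starts <- starts[!hasN]
    probes <- probes[!hasN]
  }
  out <- data.frame(start = as.integer(starts), probe = probes,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped_N") <- dropped
  out
}

#' Closed-form probe count for a tiled target
#'
#' `floor((L - probeLen) / step) + 1`, plus one flush-end probe when
#' `(L - probeLen)` is not a multiple of the step.
#'
#' @param L ungapped target length.
#' @param probeLen probe length, default 120.
#' @param tiling tiling factor, default 2.
#' @return integer probe count.
#' @export
probeCountFormula <- function(L, probeLen = 120, tiling = 2) {
  step <- probeLen / tiling
  as.integer((L - probeLen) %/% step + 1L + ((L - probeLen) %% step != 0))
}

#' Design a probe set from surviving loci
#'
#' Runs representative selection, the random kit subset and probe tiling,
#' and assembles a [ProbeSet-class]. Representatives are exported ungapped
#' (gap characters stripped) before tiling.
#'
#' @param blocks named list of surviving [ExonBlock-class] objects (names
#'   or [blockId()]s identify loci).
#' @param cladeMap named character vector `taxon -> clade`.
#' @param seed integer design seed.
#' @param kitSize loci to keep; `NULL` keeps all.
#' @param probeLen probe length, default 120.
#' @param tiling tiling factor, default 2.
#' @param outDir optional output directory for `targets.fasta`,
#'   `probes.fasta` and `design_report.tsv`.
#' @param locusGene optional named vector `locus id -> gene id` used for
#'   the distinct-gene count in the report.
#' @return list with `probeSet` ([ProbeSet-class]), `representatives`
#'   (data.frame) and `report` (one-row data.frame of design totals).
#' @export
designBaits <- function(blocks, cladeMap, seed, kitSize = NULL,
                        probeLen = 120, tiling = 2, outDir = NULL,
                        locusGene = NULL) {
  ids <- vapply(blocks, blockId, character(1L))
  names(blocks) <- ids
  keep <- if (is.null(kitSize)) sort(ids) else
    subsetKit(ids, kitSize, seed)
  blocks <- blocks[keep]

  reps <- do.call(rbind, lapply(blocks, selectRepresentatives,
                                cladeMap = cladeMap, seed = seed))
  rownames(reps) <- NULL

  probeRows <- list()
  targetSeqs <- character()
  repLens <- numeric(0)
  dropped <- 0L
  for (k in seq_len(nrow(reps))) {
    b <- blocks[[reps$locus[k]]]
    row <- as.character(b@aln[[reps$representative_id[k]]])
    ungapped <- gsub(GAP_CHAR, "", row, fixed = TRUE)
    repLens <- c(repLens, nchar(ungapped))
    hdr <- paste(reps$locus[k], reps$representative_id[k], reps$clade[k],
                 sep = "|")
    targetSeqs[hdr] <- ungapped
    tp <- tileProbes(ungapped, probeLen, tiling)
    dropped <- dropped + attr(tp, "n_dropped_N")
    if (nrow(tp)) {
      probeRows[[length(probeRows) + 1L]] <- data.frame(
        locus_id = reps$locus[k],
        representative_id = reps$representative_id[k],
        start = tp$start, probe = tp$probe, stringsAsFactors = FALSE)
    }
  }
  probeDf <- if (length(probeRows)) do.call(rbind, probeRows) else
    data.frame(locus_id = character(), representative_id = character(),
               start = integer(), probe = character())

  # target bp: per-locus consensus length = block column count (shared
  # coordinate system of the representatives); reference bp: sum over all
  # exported representative sequences
  lens <- vapply(blocks, blockLength, integer(1L))
  totalTarget <- sum(lens)
  ps <- methods::new("ProbeSet",
    probes = S4Vectors::DataFrame(probeDf),
    summary = list(n_probes = nrow(probeDf), n_loci = length(blocks),
                   total_target_bp = totalTarget, n_dropped_N = dropped))

  nGenes <- if (is.null(locusGene)) NA_integer_ else
    length(unique(unname(locusGene[keep])))
  pisProps <- vapply(blocks, function(b)
    if (length(b@aln) >= 2L) countPis(b)$proportion else NA_real_,
    numeric(1L))
  report <- data.frame(
    n_loci = length(blocks), n_genes = nGenes,
    locus_len_min = min(lens), locus_len_max = max(lens),
    locus_len_mean = mean(lens),
    pis_prop_min = min(pisProps, na.rm = TRUE),
    pis_prop_max = max(pisProps, na.rm = TRUE),
    pis_prop_mean = mean(pisProps, na.rm = TRUE),
    total_target_bp = totalTarget,
    total_reference_bp = sum(repLens),
    n_probes = nrow(probeDf), n_probes_dropped_N = dropped)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(Biostrings::BStringSet(targetSeqs),
      file.path(outDir, "targets.fasta"))
    pseqs <- setNames(probeDf$probe,
                      paste(probeDf$locus_id, probeDf$representative_id,
                            probeDf$start, sep = "|"))
    Biostrings::writeXStringSet(Biostrings::BStringSet(pseqs),
      file.path(outDir, "probes.fasta"))
    utils::write.table(report, file.path(outDir, "design_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(probeSet = ps, representatives = reps, report = report)
}
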