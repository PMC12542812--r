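#' Find split-point column runs of an ortholog alignment
#'
#' A column is a split point under either of two conditions: (i) the
#' intron-masked genomic reference marks it as `INTRON`, or (ii) every
#' transcriptome row (all non-reference rows) is gapped at that column and
#' the maximal such all-gap run is at least `minSharedGapRun` columns long.
#' Overlapping or adjacent runs from the two conditions are merged into
#' maximal runs.
#'
#' @param alignment a [LocusAlignment-class]; its `columnTrack` must be set
#'   (see [annotateColumns()]) for condition (i) to fire.
#' @param minSharedGapRun minimum length of an all-gap run to qualify as a
#'   split (default 1).
#' @param gapFraction fraction of transcriptome rows that must be gapped for
#'   condition (ii); default 1 (all rows), the strictest reading, which can
#'   never split inside a sequenced exon.
#' @return integer matrix with columns `start0`/`end0`: 0-based half-open
#'   column runs, sorted and disjoint.
#' @export
findSplitRuns <- function(alignment, minSharedGapRun = 1L,
                          gapFraction = 1.0) {
  stopifnot(methods::is(alignment, "LocusAlignment"),
            minSharedGapRun >= 1L)
  m <- alnMatrix(alignment@seqs)
  L <- ncol(m)
  intron <- if (length(alignment@columnTrack)) {
    alignment@columnTrack == "INTRON"
  } else rep(FALSE, L)

  rows <- rownames(m)
  dataRows <- if (!is.na(alignment@referenceRowId)) {
    setdiff(rows, alignment@referenceRowId)
  } else rows
  allGap <- rep(FALSE, L)
  if (length(dataRows) > 0L) {
    sub <- m[dataRows, , drop = FALSE]
    gapped <- colSums(sub == GAP_CHAR) >= gapFraction * nrow(sub)
    runs <- logicalRuns(gapped)
    keep <- (runs[, "end0"] - runs[, "start0"]) >= minSharedGapRun
    for (i in which(keep)) {
      allGap[(runs[i, "start0"] + 1L):runs[i, "end0"]] <- TRUE
    }
  }
  logicalRuns(intron | allGap)
}

#' Carve an alignment into complete exon blocks
#'
#' The complement of the split runs becomes the exon blocks, ordered along
#' the alignment with 1-based `exonIndex`. Each block's sub-alignment drops
#' the reference row and any row that is entirely gaps within the span;
#' zero-width complements are skipped.
#'
#' @param alignment a [LocusAlignment-class].
#' @param splitRuns matrix from [findSplitRuns()] (0-based half-open,
#'   disjoint, sorted).
#' @return list of [ExonBlock-class] objects.
#' @examples
#' aln <- LocusAlignment("AH1", c(t1 = "ACGTACGTAC", t2 = "ACGTACGTAC"))
#' carve(aln, cbind(start0 = 4L, end0 = 6L))
#' @export
carve <- function(alignment, splitRuns) {
  stopifnot(methods::is(alignment, "LocusAlignment"))
  L <- Biostrings::width(alignment@seqs)[1L]
  isSplit <- rep(FALSE, L)
  if (nrow(splitRuns)) {
    for (i in seq_len(nrow(splitRuns))) {
      if (splitRuns[i, "end0"] > splitRuns[i, "start0"])
        isSplit[(splitRuns[i, "start0"] + 1L):splitRuns[i, "end0"]] <- TRUE
    }
  }
  keepRuns <- logicalRuns(!isSplit)
  rows <- names(alignment@seqs)
  dataRows <- if (!is.na(alignment@referenceRowId)) {
    setdiff(rows, alignment@referenceRowId)
  } else rows
  m <- alnMatrix(alignment@seqs)

  blocks <- list()
  for (i in seq_len(nrow(keepRuns))) {
    s0 <- unname(keepRuns[i, "start0"]); e0 <- unname(keepRuns[i, "end0"])
    sub <- m[dataRows, (s0 + 1L):e0, drop = FALSE]
    notAllGap <- rowSums(sub != GAP_CHAR) > 0L
    sub <- sub[notAllGap, , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- methods::new("ExonBlock",
      orthologId = alignment@orthologId,
      exonIndex  = length(blocks) + 1L,
      span       = c(s0, e0),
      aln        = Biostrings::BStringSet(matrixAln(sub)))
  }
  blocks
}

#' Carve every alignment of a directory or list
#'
#' @param alignments list of [LocusAlignment-class] objects, or a directory
#'   of aligned FASTA files (one per ortholog; file base name = ortholog
#'   id).
#' @param referenceRowId id of the masked reference row; `NA` disables
#'   condition (i).
#' @param minSharedGapRun passed to [findSplitRuns()].
#' @param gapFraction passed to [findSplitRuns()].
#' @param maskChar mask symbol used in the reference row.
#' @param outDir optional directory; blocks are written as
#'   `<orthologId>_E<index>.fasta`.
#' @return list of [ExonBlock-class] objects across all alignments.
#' @export
carveAll <- function(alignments, referenceRowId = NA_character_,
                     minSharedGapRun = 1L, gapFraction = 1.0,
                     maskChar = "#", outDir = NULL) {
  if (is.character(alignments)) {
    files <- sort(list.files(alignments, pattern = "\\.fa(sta)?$",
                             full.names = TRUE))
    alignments <- lapply(files, function(f) {
      LocusAlignment(sub("\\.fa(sta)?$", "", basename(f)),
                     Biostrings::readBStringSet(f),
                     referenceRowId = referenceRowId, maskChar = maskChar)
    })
  }
  blocks <- list()
  for (aln in alignments) {
    if (!is.na(aln@referenceRowId) && !length(aln@columnTrack))
      aln <- annotateColumns(aln)
    runs <- findSplitRuns(aln, minSharedGapRun, gapFraction)
    blocks <- c(blocks, carve(aln, runs))
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (b in blocks) {
      Biostrings::writeXStringSet(b@aln,
        file.path(outDir, paste0(blockId(b), ".fasta")))
    }
  }
  blocks
}
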