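#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' GeneModel: a gene's span and its exon structure on a genome sequence
#'
#' Holds one gene interval together with the union of its annotated exon
#' intervals (merged across transcripts into non-overlapping runs). Genomic
#' coordinates are stored as \linkS4class{IRanges} (1-based, closed), the
#' native Bioconductor convention; exported interval tables use 0-based
#' half-open coordinates at the I/O boundary.
#'
#' @slot geneId single gene identifier.
#' @slot seqid chromosome/contig name.
#' @slot strand `"+"` or `"-"`.
#' @slot gene length-one \linkS4class{IRanges} with the gene span.
#' @slot exons \linkS4class{IRanges} of merged exon runs, sorted, contained
#'   in the gene span.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneId = "character",
    seqid  = "character",
    strand = "character",
    gene   = "IRanges",
    exons  = "IRanges"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (length(object@seqid) != 1L || !nzchar(object@seqid))
    msg <- c(msg, "seqid must be a single non-empty string")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(object@gene) != 1L)
    msg <- c(msg, "gene must be a single interval")
  if (length(object@exons) > 0L) {
    if (any(IRanges::start(object@exons) < IRanges::start(object@gene)) ||
        any(IRanges::end(object@exons) > IRanges::end(object@gene)))
      msg <- c(msg, sprintf("exon outside gene span for gene '%s'",
                            object@geneId))
    if (is.unsorted(IRanges::start(object@exons)))
      msg <- c(msg, "exons must be sorted by start")
    if (length(object@exons) > 1L) {
      s <- IRanges::start(object@exons)
      e <- IRanges::end(object@exons)
      if (any(s[-1L] <= e[-length(e)]))
        msg <- c(msg, sprintf("overlapping exons in gene '%s'", object@geneId))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param seqid contig name.
#' @param strand `"+"` or `"-"`.
#' @param gene length-one [IRanges::IRanges] gene span (1-based closed).
#' @param exons [IRanges::IRanges] of exon intervals; overlapping or
#'   book-ended intervals are merged and sorted.
#' @return a [GeneModel-class] object.
#' @export
GeneModel <- function(geneId, seqid, strand, gene, exons) {
  exons <- IRanges::reduce(exons)
  new("GeneModel", geneId = as.character(geneId), seqid = as.character(seqid),
      strand = strand, gene = gene, exons = exons)
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "on", object@seqid, object@strand, "\n")
  cat("  gene: [", IRanges::start(object@gene), ",",
      IRanges::end(object@gene), "]  exons:", length(object@exons),
      " width:", sum(IRanges::width(object@exons)), "bp\n")
})

#' LocusAlignment: one ortholog alignment, optionally with a masked
#' reference row
#'
#' Rows are equal-length aligned sequences over `{A,C,G,T,N,-}` plus the
#' mask symbol used to encode intron positions in the genome-derived
#' reference row. Stored as a \linkS4class{BStringSet} because the mask
#' symbol is outside the DNA alphabet.
#'
#' @slot orthologId locus identifier.
#' @slot seqs named \linkS4class{BStringSet}; names are sequence ids.
#' @slot referenceRowId id of the intron-masked genome row, or `NA`.
#' @slot maskChar single mask character (default `"#"`).
#' @slot columnTrack per-column status (`"EXON"`, `"INTRON"`, `"UNKNOWN"`),
#'   or length zero when not yet annotated.
#' @exportClass LocusAlignment
setClass("LocusAlignment",
  representation(
    orthologId     = "character",
    seqs           = "BStringSet",
    referenceRowId = "character",
    maskChar       = "character",
    columnTrack    = "character"
  )
)

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@seqs) < 1L)
    msg <- c(msg, "alignment needs at least one row")
  w <- Biostrings::width(object@seqs)
  if (length(unique(w)) > 1L)
    msg <- c(msg, "all rows must have equal length")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "rows must have unique names")
  if (nchar(object@maskChar) != 1L)
    msg <- c(msg, "maskChar must be a single character")
  if (!is.na(object@referenceRowId) &&
      !object@referenceRowId %in% names(object@seqs))
    msg <- c(msg, sprintf("reference row '%s' absent from alignment",
                          object@referenceRowId))
  if (length(object@columnTrack) > 0L &&
      length(object@columnTrack) != w[1L])
    msg <- c(msg, "column track length must equal alignment length")
  if (length(msg)) msg else TRUE
})

#' Construct a LocusAlignment
#'
#' @param orthologId locus id.
#' @param seqs named character vector or [Biostrings::BStringSet] of
#'   equal-length aligned rows.
#' @param referenceRowId id of the intron-masked reference row (`NA` if
#'   absent).
#' @param maskChar intron mask symbol, default `"#"`.
#' @return a [LocusAlignment-class].
#' @export
LocusAlignment <- function(orthologId, seqs, referenceRowId = NA_character_,
                           maskChar = "#") {
  if (!methods::is(seqs, "BStringSet"))
    seqs <- Biostrings::BStringSet(seqs)
  new("LocusAlignment", orthologId = as.character(orthologId), seqs = seqs,
      referenceRowId = as.character(referenceRowId), maskChar = maskChar,
      columnTrack = character())
}

setMethod("show", "LocusAlignment", function(object) {
  cat("LocusAlignment", object@orthologId, ":", length(object@seqs),
      "rows x", Biostrings::width(object@seqs)[1L], "columns\n")
  if (!is.na(object@referenceRowId))
    cat("  reference row:", object@referenceRowId, "\n")
  if (length(object@columnTrack))
    cat("  column track:", sum(object@columnTrack == "INTRON"),
        "intron columns\n")
})

#' ExonBlock: one carved exon sub-alignment
#'
#' @slot orthologId parent locus id.
#' @slot exonIndex 1-based ordinal of the exon along the parent alignment.
#' @slot span integer length-2, half-open `[start, end)` column span in
#'   0-based parent coordinates.
#' @slot aln named \linkS4class{BStringSet}: the sub-alignment with the
#'   reference row dropped and all-gap rows removed.
#' @exportClass ExonBlock
setClass("ExonBlock",
  representation(
    orthologId = "character",
    exonIndex  = "integer",
    span       = "integer",
    aln        = "BStringSet"
  )
)

setValidity("ExonBlock", function(object) {
  msg <- character()
  if (length(object@span) != 2L || object@span[2L] <= object@span[1L])
    msg <- c(msg, "span must be a half-open [start, end) with end > start")
  if (length(object@aln) > 0L) {
    w <- Biostrings::width(object@aln)
    if (any(w != object@span[2L] - object@span[1L]))
      msg <- c(msg, "sub-alignment width must equal span width")
    gapOnly <- vapply(as.character(object@aln), function(s) {
      all(strsplit(s, "", fixed = TRUE)[[1L]] == "-")
    }, logical(1L))
    if (any(gapOnly))
      msg <- c(msg, "sub-alignment must not contain all-gap rows")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExonBlock", function(object) {
  cat(sprintf("ExonBlock %s_E%d: columns [%d, %d), %d rows\n",
              object@orthologId, object@exonIndex,
              object@span[1L], object@span[2L], length(object@aln)))
})

#' Locus id of an exon block (`<orthologId>_E<exonIndex>`)
#' @param block an [ExonBlock-class].
#' @return character id.
#' @export
blockId <- function(block) {
  sprintf("%s_E%d", block@orthologId, block@exonIndex)
}

#' Alignment width (column count) of an exon block
#'
#' Exon length is defined as the block's alignment column count, including
#' internal gap columns; downstream length filters operate on this value.
#'
#' @param block an [ExonBlock-class].
#' @return integer number of columns.
#' @export
blockLength <- function(block) {
  as.integer(block@span[2L] - block@span[1L])
}

#' Rows of an exon block as a character matrix
#' @param block an [ExonBlock-class].
#' @return character matrix, one row per sequence.
#' @export
blockMatrix <- function(block) {
  alnMatrix(block@aln)
}

#' DesignThresholds: every numeric gate of the design cascade
#'
#' Defaults mirror the published design conditions: exons longer than 700 bp
#' enter the cascade, more than 2% parsimony-informative sites are required,
#' sequences with gap proportion strictly above 0.5 are removed, surviving
#' blocks need at least 800 columns, at least 75% mean pairwise identity and
#' at least 10 sequences, loci with more than 3 duplications in a diploid
#' reference taxon are discarded, and 120-nt probes are tiled at 2x for a
#' 1000-locus kit. Tree-side defaults: collapse supports below 70, trim
#' columns with more than 70% missing data, require 15 ingroup taxa for MO
#' orthologs and 10 for orthogroup extraction.
#'
#' @slot minExonLenPass1 pass-1 length gate (strict `>`), default 700.
#' @slot minPisFraction PIS-proportion gate (strict `>`), default 0.02.
#' @slot maxGapRatio per-sequence gap-ratio ceiling (remove if strictly
#'   greater), default 0.5.
#' @slot minExonLenPass2 pass-2 length gate (`>=`), default 800.
#' @slot minPairwiseIdentity mean pairwise identity gate in percent (`>=`),
#'   default 75.
#' @slot minSequences occupancy gate (`>=`), default 10.
#' @slot maxMeanGapRatio all-row mean gap-ratio ceiling used as the
#'   deterministic proxy for the "excessive gaps" manual screen, default 0.25.
#' @slot requireBothClades logical, default `TRUE`.
#' @slot maxDuplications diploid-reference duplication ceiling (remove if
#'   strictly greater), default 3.
#' @slot kitSize number of loci drawn for the kit, default 1000.
#' @slot probeLen probe length in nt, default 120.
#' @slot tiling tiling factor, default 2.
#' @slot moMinIngroup minimum ingroup taxa for an MO ortholog, default 15.
#' @slot orthogroupMinIngroup minimum ingroup taxa for an orthogroup,
#'   default 10.
#' @slot columnMissingTrim missing-data fraction above which a column is
#'   trimmed (strict `>`), default 0.70.
#' @slot supportCollapse support below which a branch is collapsed (strict
#'   `<`), default 70.
#' @exportClass DesignThresholds
setClass("DesignThresholds",
  representation(
    minExonLenPass1      = "numeric",
    minPisFraction       = "numeric",
    maxGapRatio          = "numeric",
    minExonLenPass2      = "numeric",
    minPairwiseIdentity  = "numeric",
    minSequences         = "numeric",
    maxMeanGapRatio      = "numeric",
    requireBothClades    = "logical",
    maxDuplications      = "numeric",
    kitSize              = "numeric",
    probeLen             = "numeric",
    tiling               = "numeric",
    moMinIngroup         = "numeric",
    orthogroupMinIngroup = "numeric",
    columnMissingTrim    = "numeric",
    supportCollapse      = "numeric"
  )
)

setValidity("DesignThresholds", function(object) {
  msg <- character()
  frac <- c(minPisFraction = object@minPisFraction,
            maxGapRatio = object@maxGapRatio,
            maxMeanGapRatio = object@maxMeanGapRatio,
            columnMissingTrim = object@columnMissingTrim)
  bad <- frac < 0 | frac > 1
  if (any(bad))
    msg <- c(msg, paste(names(frac)[bad], "must lie in [0, 1]"))
  if (object@minPairwiseIdentity < 0 || object@minPairwiseIdentity > 100)
    msg <- c(msg, "minPairwiseIdentity must lie in [0, 100]")
  pos <- c(minExonLenPass1 = object@minExonLenPass1,
           minExonLenPass2 = object@minExonLenPass2,
           minSequences = object@minSequences,
           kitSize = object@kitSize, probeLen = object@probeLen,
           tiling = object@tiling)
  if (any(pos <= 0))
    msg <- c(msg, paste(names(pos)[pos <= 0], "must be positive"))
  if (object@maxDuplications < 0)
    msg <- c(msg, "maxDuplications must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct the design thresholds
#'
#' @param ... named overrides of any slot of
#'   [DesignThresholds-class]; unnamed defaults are the published values.
#' @return a [DesignThresholds-class].
#' @examples
#' designThresholds()
#' designThresholds(kitSize = 50, minSequences = 4)
#' @export
designThresholds <- function(...) {
  defaults <- list(
    minExonLenPass1 = 700, minPisFraction = 0.02, maxGapRatio = 0.5,
    minExonLenPass2 = 800, minPairwiseIdentity = 75, minSequences = 10,
    maxMeanGapRatio = 0.25, requireBothClades = TRUE, maxDuplications = 3,
    kitSize = 1000, probeLen = 120, tiling = 2, moMinIngroup = 15,
    orthogroupMinIngroup = 10, columnMissingTrim = 0.70,
    supportCollapse = 70
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  do.call(new, c(list("DesignThresholds"), defaults))
}

setMethod("show", "DesignThresholds", function(object) {
  cat("DesignThresholds:\n")
  cat(sprintf("  pass-1 length > %g, PIS > %g, row gap ratio <= %g\n",
              object@minExonLenPass1, object@minPisFraction,
              object@maxGapRatio))
  cat(sprintf("  pass-2 length >= %g, identity >= %g%%, sequences >= %g\n",
              object@minExonLenPass2, object@minPairwiseIdentity,
              object@minSequences))
  cat(sprintf("  duplications <= %g, kit %g loci, %g-nt probes at %gx\n",
              object@maxDuplications, object@kitSize, object@probeLen,
              object@tiling))
  cat(sprintf("  MO ingroup >= %g, orthogroup ingroup >= %g,",
              object@moMinIngroup, object@orthogroupMinIngroup))
  cat(sprintf(" collapse < %g, trim > %g missing\n",
              object@supportCollapse, object@columnMissingTrim))
})

#' ProbeSet: tiled probes with provenance
#'
#' @slot probes \linkS4class{DataFrame} with columns `locus_id`,
#'   `representative_id`, `start` (0-based offset on the ungapped
#'   representative) and `probe` (sequence).
#' @slot summary named list: `n_probes`, `n_loci`, `total_target_bp`,
#'   `n_dropped_N`.
#' @exportClass ProbeSet
setClass("ProbeSet",
  representation(probes = "DataFrame", summary = "list")
)

setValidity("ProbeSet", function(object) {
  msg <- character()
  need <- c("locus_id", "representative_id", "start", "probe")
  if (!all(need %in% colnames(object@probes)))
    msg <- c(msg, paste("probes must have columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProbeSet", function(object) {
  cat("ProbeSet:", nrow(object@probes), "probes over",
      object@summary$n_loci, "loci,",
      object@summary$total_target_bp, "target bp\n")
})

#' Probe table of a ProbeSet
#' @param x a [ProbeSet-class].
#' @return a [S4Vectors::DataFrame] of probes.
#' @export
probes <- function(x) x@probes

#' Summary list of a ProbeSet
#' @param x a [ProbeSet-class].
#' @return named list of design totals.
#' @export
probeSummary <- function(x) x@summary
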