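#' Count parsimony-informative sites of an exon block
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' nucleotide states (A/C/G/T) each occur in at least two sequences. Gaps,
#' N and other ambiguity codes carry no state.
#'
#' @param block an [ExonBlock-class] (or a character matrix of aligned
#'   rows) with at least two rows.
#' @return list with `count` and `proportion` (count / block length).
#' @examples
#' b <- exonBlockFromRows(c(a = "AAT", b = "AAT", c = "AAC", d = "AAC"))
#' countPis(b)  # 1 informative column out of 3
#' @export
countPis <- function(block) {
  m <- if (is.matrix(block)) block else blockMatrix(block)
  if (nrow(m) < 2L)
    stop("parsimony-informative sites are undefined for fewer than 2 rows")
  informative <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = NUC_STATES))
    sum(tab >= 2L) >= 2L
  }, logical(1L))
  n <- sum(informative)
  list(count = n, proportion = n / ncol(m))
}

#' Gap proportion of one aligned sequence
#'
#' @param seq a single aligned sequence (character scalar).
#' @return fraction of gap characters in the sequence.
#' @examples
#' gapRatio("A-T-")   # 0.5
#' gapRatio("----A")  # 0.8
#' @export
gapRatio <- function(seq) {
  seq <- as.character(seq)
  if (!nzchar(seq)) stop("gap ratio is undefined for an empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sum(chars == GAP_CHAR) / length(chars)
}

#' Mean pairwise identity of an exon block (percent)
#'
#' For each unordered row pair, identity = matching columns / compared
#' columns, where compared columns exclude any column gapped in either
#' member of the pair. Pairs with no compared columns are skipped; the
#' result is the unweighted mean over the retained pairs, times 100.
#'
#' @param block an [ExonBlock-class] or character matrix with >= 2 rows.
#' @return mean pairwise identity in `[0, 100]`.
#' @export
meanPairwiseIdentity <- function(block) {
  m <- if (is.matrix(block)) block else blockMatrix(block)
  if (nrow(m) < 2L)
    stop("pairwise identity is undefined for fewer than 2 rows")
  ids <- c()
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):nrow(m)) {
      ok <- m[i, ] != GAP_CHAR & m[j, ] != GAP_CHAR
      if (!any(ok)) next
      ids <- c(ids, sum(m[i, ok] == m[j, ok]) / sum(ok))
    }
  }
  if (!length(ids))
    stop("all row pairs have zero compared columns")
  mean(ids) * 100
}

#' Flag a block containing internal stop codons
#'
#' Each row is read ungapped; for each of the three frames the internal
#' stop codons (TAA/TAG/TGA, excluding a stop in the row's final complete
#' codon) are counted, and the frame minimising the total across rows is
#' selected for the block. The block is flagged when any row still carries
#' an internal stop in that frame.
#'
#' @param block an [ExonBlock-class] or character matrix.
#' @return `TRUE` if the block should be removed.
#' @export
screenStopCodons <- function(block) {
  m <- if (is.matrix(block)) block else blockMatrix(block)
  stopsPerFrame <- function(row) {
    s <- row[row != GAP_CHAR]
    vapply(0:2, function(f) internalStops(s, f), integer(1L))
  }
  counts <- t(apply(m, 1L, stopsPerFrame))   # rows x 3 frames
  best <- which.min(colSums(counts))
  any(counts[, best] > 0L)
}

# Internal stop count of an ungapped character vector in frame f (0/1/2):
# stops among complete codons, excluding the last complete codon.
internalStops <- function(chars, f) {
  n <- length(chars)
  starts <- seq.int(f + 1L, by = 3L,
                    length.out = max(0L, (n - f) %/% 3L))
  if (length(starts) <= 1L) return(0L)
  starts <- starts[-length(starts)]   # drop terminal codon
  codons <- vapply(starts, function(s)
    paste0(chars[s:(s + 2L)], collapse = ""), character(1L))
  sum(codons %in% c("TAA", "TAG", "TGA"))
}

#' Mean gap ratio across the rows of a block
#' @param block an [ExonBlock-class] or character matrix.
#' @return mean of the per-row gap proportions.
#' @export
meanGapRatio <- function(block) {
  m <- if (is.matrix(block)) block else blockMatrix(block)
  mean(rowSums(m == GAP_CHAR) / ncol(m))
}

#' Apply the design filtering cascade to carved exon blocks
#'
#' Stages, in order: (1) pass-1 length (strictly greater than
#' `minExonLenPass1` columns); (2) parsimony-informative proportion
#' (strictly greater than `minPisFraction`); (3) per-sequence gap-ratio
#' screen, which removes rows whose gap proportion strictly exceeds
#' `maxGapRatio` and re-evaluates the reduced block; (4) pass-2 length
#' (`>= minExonLenPass2`), mean pairwise identity
#' (`>= minPairwiseIdentity`) and occupancy (`>= minSequences` rows);
#' (5) stop-codon / excessive-gap screen (reject on internal stops in the
#' best frame, or all-row mean gap ratio above `maxMeanGapRatio`); (6) clade
#' coverage (every clade label of `cladeMap` represented when
#' `requireBothClades`).
#'
#' Every measurement is recorded in a filter ledger; a block rejected at
#' stage k has no entries for later stages.
#'
#' @param blocks list of [ExonBlock-class] objects.
#' @param thresholds a [DesignThresholds-class].
#' @param cladeMap named character vector `taxon -> clade label` covering
#'   every taxon appearing in the blocks.
#' @return list with `survivors` (blocks, possibly with rows removed at
#'   stage 3) and `ledger` (data.frame: locus, stage, metric, value,
#'   threshold, verdict).
#' @export
applyCascade <- function(blocks, thresholds = designThresholds(),
                         cladeMap) {
  stopifnot(methods::is(thresholds, "DesignThresholds"))
  blocks <- blocks[order(vapply(blocks, blockId, character(1L)))]
  taxa <- unique(unlist(lapply(blocks, function(b) names(b@aln))))
  missing <- setdiff(taxa, names(cladeMap))
  if (length(missing))
    stop("taxa missing from the clade map: ",
         paste(missing, collapse = ", "))
  clades <- sort(unique(unname(cladeMap)))

  led <- list()
  note <- function(locus, stage, metric, value, threshold, verdict) {
    led[[length(led) + 1L]] <<- data.frame(
      locus = locus, stage = stage, metric = metric,
      value = value, threshold = threshold, verdict = verdict,
      stringsAsFactors = FALSE)
  }

  survivors <- list()
  for (b in blocks) {
    id <- blockId(b)

    len <- blockLength(b)
    ok <- len > thresholds@minExonLenPass1
    note(id, "length_pass1", "length", len, thresholds@minExonLenPass1,
         if (ok) "pass" else "fail")
    if (!ok) next

    pis <- countPis(b)
    ok <- pis$proportion > thresholds@minPisFraction
    note(id, "pis", "pis_proportion", pis$proportion,
         thresholds@minPisFraction, if (ok) "pass" else "fail")
    if (!ok) next

    # stage 3 removes sequences, not loci
    m <- blockMatrix(b)
    gr <- rowSums(m == GAP_CHAR) / ncol(m)
    drop <- gr > thresholds@maxGapRatio
    for (r in which(drop))
      note(id, "gap_ratio", paste0("gap_ratio:", rownames(m)[r]), gr[r],
           thresholds@maxGapRatio, "row_removed")
    if (any(drop)) {
      keep <- m[!drop, , drop = FALSE]
      b <- methods::new("ExonBlock", orthologId = b@orthologId,
                        exonIndex = b@exonIndex, span = b@span,
                        aln = Biostrings::BStringSet(matrixAln(keep)))
    }

    n <- length(b@aln)
    ok <- len >= thresholds@minExonLenPass2
    note(id, "length_pass2", "length", len, thresholds@minExonLenPass2,
         if (ok) "pass" else "fail")
    if (!ok) next
    ok <- n >= thresholds@minSequences
    note(id, "min_sequences", "n_sequences", n, thresholds@minSequences,
         if (ok) "pass" else "fail")
    if (!ok) next
    ident <- meanPairwiseIdentity(b)
    ok <- ident >= thresholds@minPairwiseIdentity
    note(id, "pairwise_identity", "mean_pairwise_identity", ident,
         thresholds@minPairwiseIdentity, if (ok) "pass" else "fail")
    if (!ok) next

    hasStops <- screenStopCodons(b)
    note(id, "stop_codons", "has_internal_stop", as.numeric(hasStops), 0,
         if (hasStops) "fail" else "pass")
    if (hasStops) next
    mgr <- meanGapRatio(b)
    ok <- mgr <= thresholds@maxMeanGapRatio
    note(id, "mean_gap_ratio", "mean_gap_ratio", mgr,
         thresholds@maxMeanGapRatio, if (ok) "pass" else "fail")
    if (!ok) next

    if (thresholds@requireBothClades) {
      present <- sort(unique(unname(cladeMap[names(b@aln)])))
      ok <- all(clades %in% present)
      note(id, "clade_coverage", "n_clades_present", length(present),
           length(clades), if (ok) "pass" else "fail")
      if (!ok) next
    }

    survivors[[length(survivors) + 1L]] <- b
  }
  ledger <- if (length(led)) do.call(rbind, led) else
    data.frame(locus = character(), stage = character(),
               metric = character(), value = numeric(),
               threshold = numeric(), verdict = character())
  list(survivors = survivors, ledger = ledger)
}

#' Build an ExonBlock directly from aligned rows (mainly for tests and
#' examples)
#'
#' @param rows named character vector of equal-length aligned rows.
#' @param orthologId locus id, default `"locus"`.
#' @param exonIndex exon ordinal, default 1.
#' @param start0 0-based start column in a notional parent alignment.
#' @return an [ExonBlock-class].
#' @export
exonBlockFromRows <- function(rows, orthologId = "locus", exonIndex = 1L,
                              start0 = 0L) {
  w <- unique(nchar(rows))
  stopifnot(length(w) == 1L)
  methods::new("ExonBlock", orthologId = orthologId,
               exonIndex = as.integer(exonIndex),
               span = c(as.integer(start0), as.integer(start0) + w),
               aln = Biostrings::BStringSet(rows))
}

#' Summary statistics table for a set of exon blocks
#'
#' @param blocks list of [ExonBlock-class] objects.
#' @param cladeMap optional named vector `taxon -> clade`.
#' @return data.frame with one row per block: locus, length,
#'   pis_count, pis_proportion, mean_pairwise_identity, n_sequences,
#'   n_clades.
#' @export
locusStats <- function(blocks, cladeMap = NULL) {
  do.call(rbind, lapply(blocks, function(b) {
    pis <- if (length(b@aln) >= 2L) countPis(b) else
      list(count = NA_integer_, proportion = NA_real_)
    ident <- if (length(b@aln) >= 2L) meanPairwiseIdentity(b) else NA_real_
    data.frame(
      locus = blockId(b), length = blockLength(b),
      pis_count = pis$count, pis_proportion = pis$proportion,
      mean_pairwise_identity = ident, n_sequences = length(b@aln),
      n_clades = if (is.null(cladeMap)) NA_integer_ else
        length(unique(unname(cladeMap[names(b@aln)]))),
      stringsAsFactors = FALSE)
  }))
}
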