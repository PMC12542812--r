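#' @importFrom rtracklayer import export
#' @importFrom GenomicRanges GRanges seqnames strand ranges
#' @importFrom IRanges IRanges reduce setdiff shift width start end
NULL

#' Parse gene models from a GFF3 annotation
#'
#' Reads `gene` and `exon` features and builds one [GeneModel-class] per
#' gene. Exons are attached to their gene either directly (`Parent` = gene
#' id) or through an intermediate `mRNA`/transcript feature; for genes with
#' several transcripts the exon set is the union of all transcript exons,
#' merged into non-overlapping runs.
#'
#' @param gffFile path to a GFF3 file with `gene` and `exon` features
#'   carrying `ID`/`Parent` attributes.
#' @return named list of [GeneModel-class] objects (names = gene ids).
#' @examples
#' fx <- simGenome(fixtureSpec(nGenes = 2), seed = 1, dir = tempfile())
#' parseGeneModels(fx$gff)
#' @export
parseGeneModels <- function(gffFile) {
  gr <- tryCatch(rtracklayer::import(gffFile, format = "gff3"),
                 error = function(e)
                   stop("GFF3 parse error in '", gffFile, "': ",
                        conditionMessage(e), call. = FALSE))
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  if (length(genes) == 0L)
    stop("no gene features found in '", gffFile, "'")
  if (length(exons) == 0L)
    stop("no exon features found in '", gffFile, "'")
  geneIds <- as.character(genes$ID)
  if (anyNA(geneIds))
    stop("gene feature without an ID attribute in '", gffFile, "'")

  # map transcript-level feature IDs to their parent gene
  txParent <- character()
  tx <- gr[!type %in% c("gene", "exon")]
  if (length(tx)) {
    txIds <- as.character(tx$ID)
    txPar <- vapply(tx$Parent, function(p)
      if (length(p)) as.character(p)[1L] else NA_character_, character(1L))
    ok <- !is.na(txIds) & !is.na(txPar)
    txParent <- setNames(txPar[ok], txIds[ok])
  }

  exonGene <- vapply(seq_along(exons), function(i) {
    p <- exons$Parent[[i]]
    if (length(p) == 0L)
      stop("exon without a Parent attribute in '", gffFile, "'")
    p <- as.character(p)[1L]
    if (p %in% geneIds) p
    else if (p %in% names(txParent)) unname(txParent[[p]])
    else p
  }, character(1L))

  out <- vector("list", length(genes))
  names(out) <- geneIds
  for (i in seq_along(genes)) {
    gid <- geneIds[i]
    ex <- exons[exonGene == gid]
    exr <- IRanges::reduce(ranges(ex))
    g <- ranges(genes)[i]
    if (length(exr) &&
        (any(IRanges::start(exr) < IRanges::start(g)) ||
         any(IRanges::end(exr) > IRanges::end(g))))
      stop("exon outside gene span for gene '", gid, "'")
    out[[i]] <- GeneModel(
      geneId = gid,
      seqid  = as.character(seqnames(genes))[i],
      strand = as.character(strand(genes))[i],
      gene   = g,
      exons  = exr
    )
  }
  out
}

#' Gene-local intron intervals of a gene model
#'
#' Subtracts the exon runs from the gene span; the complement (the introns)
#' is returned in gene-local coordinates on the forward genomic orientation
#' of the gene (1-based closed [IRanges::IRanges]). Intervals are sorted,
#' non-overlapping and non-adjacent; the result is empty when the exons tile
#' the gene.
#'
#' @param gene a [GeneModel-class].
#' @return [IRanges::IRanges] of gene-local intron runs.
#' @examples
#' gm <- GeneModel("g", "chr", "+", IRanges::IRanges(1, 300),
#'                 IRanges::IRanges(c(1, 201), c(100, 300)))
#' subtractExons(gm)  # one intron, positions 101..200
#' @export
subtractExons <- function(gene) {
  stopifnot(methods::is(gene, "GeneModel"))
  introns <- IRanges::setdiff(gene@gene, gene@exons)
  IRanges::shift(introns, -(IRanges::start(gene@gene) - 1L))
}

#' Intron-masked gene sequence
#'
#' Extracts the gene subsequence from the genome (reverse-complemented for
#' strand `-`, after which gene-local coordinates run 5'->3' with the
#' transcript), and replaces every intron position by the mask symbol. Exon
#' characters are left untouched.
#'
#' @param genome named [Biostrings::DNAStringSet] (or path to a genome
#'   FASTA).
#' @param gene a [GeneModel-class].
#' @param maskChar single mask character, default `"#"`.
#' @return list with `geneId`, `sequence` (masked gene string, transcribed
#'   orientation), and `intronRuns` ([IRanges::IRanges], gene-local in
#'   transcribed orientation).
#' @export
maskGene <- function(genome, gene, maskChar = "#") {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(gene, "GeneModel"))
  nm <- sub("\\s.*$", "", names(genome))
  idx <- match(gene@seqid, nm)
  if (is.na(idx))
    stop("seqid '", gene@seqid, "' not found in genome FASTA")
  contig <- genome[[idx]]
  if (IRanges::end(gene@gene) > length(contig))
    stop("gene '", gene@geneId, "' extends beyond contig '",
         gene@seqid, "' (", length(contig), " bp)")
  s <- as.character(Biostrings::subseq(contig,
                                       start = IRanges::start(gene@gene),
                                       end = IRanges::end(gene@gene)))
  introns <- subtractExons(gene)   # forward gene-local
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (length(introns)) {
    pos <- unlist(mapply(seq.int, IRanges::start(introns),
                         IRanges::end(introns), SIMPLIFY = FALSE))
    chars[pos] <- maskChar
  }
  if (gene@strand == "-") {
    seqOut <- revCompMasked(paste0(chars, collapse = ""))
    runsOut <- if (length(introns)) {
      IRanges::IRanges(start = L - IRanges::end(introns) + 1L,
                       end = L - IRanges::start(introns) + 1L)
    } else IRanges::IRanges()
    runsOut <- runsOut[order(IRanges::start(runsOut))]
  } else {
    seqOut <- paste0(chars, collapse = "")
    runsOut <- introns
  }
  list(geneId = gene@geneId, sequence = seqOut, intronRuns = runsOut)
}

#' Annotate alignment columns from the masked reference row
#'
#' A column is `INTRON` where the reference row carries the mask symbol,
#' `EXON` where it carries a nucleotide (or N), and `UNKNOWN` where the
#' reference is gapped. The track is attached to the returned alignment and
#' drives split condition (i) during carving.
#'
#' @param alignment a [LocusAlignment-class].
#' @param referenceRowId id of the masked reference row; defaults to the
#'   alignment's `referenceRowId`.
#' @return the alignment with its `columnTrack` slot filled.
#' @export
annotateColumns <- function(alignment, referenceRowId = NULL) {
  stopifnot(methods::is(alignment, "LocusAlignment"))
  rid <- referenceRowId %||% alignment@referenceRowId
  if (is.na(rid) || !rid %in% names(alignment@seqs))
    stop("reference row '", rid, "' absent from alignment '",
         alignment@orthologId, "'")
  ref <- strsplit(as.character(alignment@seqs[[rid]]), "", fixed = TRUE)[[1L]]
  track <- ifelse(ref == alignment@maskChar, "INTRON",
                  ifelse(ref == GAP_CHAR, "UNKNOWN", "EXON"))
  alignment@referenceRowId <- rid
  alignment@columnTrack <- track
  methods::validObject(alignment)
  alignment
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mask introns for every gene of an annotated genome
#'
#' Convenience wrapper: parses the annotation, derives intron intervals and
#' writes (optionally) a masked-gene FASTA plus an intron-interval TSV
#' (`gene_id  start  end`, 0-based half-open, transcribed orientation).
#'
#' @param gffFile GFF3 annotation path.
#' @param genomeFile genome FASTA path.
#' @param outDir output directory, or `NULL` to skip writing.
#' @param maskChar mask symbol, default `"#"`.
#' @return named list of [maskGene()] results, one per gene.
#' @export
maskIntrons <- function(gffFile, genomeFile, outDir = NULL, maskChar = "#") {
  models <- parseGeneModels(gffFile)
  genome <- Biostrings::readDNAStringSet(genomeFile)
  masked <- lapply(models, function(gm) maskGene(genome, gm, maskChar))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seqs <- Biostrings::BStringSet(vapply(masked, `[[`, "", "sequence"))
    names(seqs) <- vapply(masked, `[[`, "", "geneId")
    Biostrings::writeXStringSet(seqs,
      filepath = file.path(outDir, "masked_genes.fasta"))
    rows <- do.call(rbind, lapply(masked, function(m) {
      if (!length(m$intronRuns)) return(NULL)
      data.frame(gene_id = m$geneId,
                 start = IRanges::start(m$intronRuns) - 1L,
                 end = IRanges::end(m$intronRuns))
    }))
    if (is.null(rows))
      rows <- data.frame(gene_id = character(), start = integer(),
                         end = integer())
    utils::write.table(rows, file.path(outDir, "intron_intervals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  masked
}
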