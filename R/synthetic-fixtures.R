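#' Specification of a synthetic study system
#'
#' The generator emulates the inputs of an exon-based bait design: an
#' annotated reference genome with multi-exon genes, per-gene ortholog
#' alignments of transcript rows from a set of taxa split into two major
#' clades, and homolog gene trees with duplications planted on chosen
#' species-tree branches. Defaults reflect the study conditions the design
#' thresholds were written for: 29 taxa in two clades, exon lengths
#' spanning the 700/800-bp gates, and a per-site substitution probability
#' small enough that within-clade identity stays above the 75% gate.
#'
#' @param nGenes number of genes, default 20.
#' @param exonsPerGene integer range (length-2) of exon counts per gene,
#'   default `c(1, 6)`.
#' @param exonLenRange exon length range in bp, default `c(120, 1100)`.
#' @param intronLenRange intron length range in bp, default `c(60, 400)`.
#' @param nTaxa number of taxa, default 29 (split into clade1/clade2; the
#'   first `ceiling(nTaxa/2)` taxa form clade1).
#' @param subProb per-site, per-taxon substitution probability relative to
#'   the reference transcript, default 0.03.
#' @param exonDelProb probability that a given taxon loses a given exon
#'   entirely (creates gap runs), default 0.05.
#' @param sharedDelProb probability that an exon is deleted in every taxon
#'   (creates the all-row gap runs of split condition ii), default 0.
#' @param dupPlan named numeric vector: species-tree branch id (sorted
#'   clade taxa, comma-collapsed) -> probability that a homolog tree
#'   duplicates that clade; default empty.
#' @return a `fixtureSpec` list.
#' @export
fixtureSpec <- function(nGenes = 20, exonsPerGene = c(1, 6),
                        exonLenRange = c(120, 1100),
                        intronLenRange = c(60, 400), nTaxa = 29,
                        subProb = 0.03, exonDelProb = 0.05,
                        sharedDelProb = 0, dupPlan = numeric()) {
  stopifnot(nGenes >= 1, all(exonLenRange > 0), all(intronLenRange > 0),
            subProb >= 0, subProb <= 1, exonDelProb >= 0, exonDelProb <= 1,
            sharedDelProb >= 0, sharedDelProb <= 1, nTaxa >= 2)
  taxa <- sprintf("taxon%02d", seq_len(nTaxa))
  clade <- setNames(ifelse(seq_len(nTaxa) <= ceiling(nTaxa / 2),
                           "clade1", "clade2"), taxa)
  structure(list(nGenes = nGenes, exonsPerGene = exonsPerGene,
                 exonLenRange = exonLenRange,
                 intronLenRange = intronLenRange,
                 taxa = taxa, cladeMap = clade, subProb = subProb,
                 exonDelProb = exonDelProb, sharedDelProb = sharedDelProb,
                 dupPlan = dupPlan),
            class = "fixtureSpec")
}

randSeq <- function(n) {
  paste(sample(NUC_STATES, n, replace = TRUE), collapse = "")
}

# coding-like sequence of length n: non-stop codons in frame 0, so the
# spliced transcripts stay free of internal stops by construction
randCodingSeq <- function(n) {
  ncod <- ceiling(n / 3)
  substr(paste(sample(NONSTOP_CODONS, ncod, replace = TRUE),
               collapse = ""), 1L, n)
}

#' Simulate a genome and its annotation with known exon structure
#'
#' Genes are laid head-to-tail on one contig with 100-bp spacers; strands
#' alternate. Writes a genome FASTA and a GFF3 (gene, mRNA and exon
#' features) and returns a truth table with every exon interval.
#'
#' @param spec a [fixtureSpec()].
#' @param seed integer seed (all randomness derives from it).
#' @param dir output directory (created).
#' @return list with `fasta`, `gff` (paths), `truth` (data.frame: gene_id,
#'   strand, gene_start, gene_end, exon_index, exon_start, exon_end; all
#'   1-based closed genomic), and `geneLocal` (data.frame of gene-local
#'   exon spans in transcribed orientation: gene_id, exon_index, start,
#'   end, 1-based closed).
#' @export
simGenome <- function(spec, seed, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withSeed(substreamSeed(seed, "genome"), {
    spacer <- 100L
    pieces <- character()
    truth <- list()
    pos <- 0L
    for (g in seq_len(spec$nGenes)) {
      gid <- sprintf("gene%03d", g)
      k <- sample(seq(spec$exonsPerGene[1L], spec$exonsPerGene[2L]), 1L)
      exLens <- sample(seq(spec$exonLenRange[1L], spec$exonLenRange[2L]),
                       k, replace = TRUE)
      inLens <- if (k > 1L)
        sample(seq(spec$intronLenRange[1L], spec$intronLenRange[2L]),
               k - 1L, replace = TRUE) else integer()
      geneLen <- sum(exLens) + sum(inLens)
      strand <- if (g %% 2L == 1L) "+" else "-"
      # build the gene in transcribed orientation: the spliced transcript
      # is coding-like (non-stop codons), introns are unconstrained
      exOrderT <- if (strand == "+") seq_len(k) else rev(seq_len(k))
      spliced <- randCodingSeq(sum(exLens))
      bnd <- cumsum(exLens[exOrderT])
      chunksT <- substring(spliced, c(1L, bnd[-k] + 1L), bnd)
      inLensT <- if (strand == "+") inLens else rev(inLens)
      seqT <- chunksT[1L]
      for (i in seq_len(k - 1L))
        seqT <- paste0(seqT, randSeq(inLensT[i]), chunksT[i + 1L])
      geneSeq <- if (strand == "+") seqT else revCompMasked(seqT)
      pieces <- c(pieces, randSeq(spacer), geneSeq)
      geneStart <- pos + spacer + 1L
      # exon intervals inside the gene (forward genomic order)
      off <- geneStart - 1L
      exStarts <- integer(k); exEnds <- integer(k)
      cur <- 0L
      for (i in seq_len(k)) {
        exStarts[i] <- off + cur + 1L
        exEnds[i] <- off + cur + exLens[i]
        cur <- cur + exLens[i] + if (i < k) inLens[i] else 0L
      }
      truth[[g]] <- data.frame(
        gene_id = gid, strand = strand, gene_start = geneStart,
        gene_end = geneStart + geneLen - 1L,
        exon_index = seq_len(k), exon_start = exStarts, exon_end = exEnds,
        stringsAsFactors = FALSE)
      pos <- pos + spacer + geneLen
    }
    genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(genome) <- "chr1"
    fastaPath <- file.path(dir, "genome.fasta")
    Biostrings::writeXStringSet(genome, fastaPath)

    truthDf <- do.call(rbind, truth)
    gffPath <- file.path(dir, "annotation.gff3")
    writeFixtureGff(truthDf, gffPath)

    geneLocal <- do.call(rbind, lapply(split(truthDf, truthDf$gene_id),
                                       geneLocalSpans))
    rownames(geneLocal) <- NULL
    list(fasta = fastaPath, gff = gffPath, truth = truthDf,
         geneLocal = geneLocal)
  })
}

# gene-local exon spans in transcribed orientation (1-based closed)
geneLocalSpans <- function(tg) {
  gs <- tg$gene_start[1L]; ge <- tg$gene_end[1L]
  if (tg$strand[1L] == "+") {
    s <- tg$exon_start - gs + 1L
    e <- tg$exon_end - gs + 1L
    idx <- tg$exon_index
  } else {
    s <- ge - tg$exon_end + 1L
    e <- ge - tg$exon_start + 1L
    o <- order(s)
    s <- s[o]; e <- e[o]
    idx <- seq_along(s)
  }
  data.frame(gene_id = tg$gene_id[1L], exon_index = idx, start = s, end = e,
             stringsAsFactors = FALSE)
}

writeFixtureGff <- function(truthDf, path) {
  lines <- c("##gff-version 3")
  for (gid in unique(truthDf$gene_id)) {
    tg <- truthDf[truthDf$gene_id == gid, , drop = FALSE]
    st <- tg$strand[1L]
    lines <- c(lines,
      sprintf("chr1\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              tg$gene_start[1L], tg$gene_end[1L], st, gid),
      sprintf("chr1\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              tg$gene_start[1L], tg$gene_end[1L], st, gid, gid),
      sprintf("chr1\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
              tg$exon_start, tg$exon_end, st, gid, tg$exon_index, gid))
  }
  writeLines(lines, path)
}

#' Simulate per-gene ortholog alignments with a masked reference row
#'
#' For each gene the spliced reference transcript is evolved independently
#' per taxon under per-site uniform substitution; optionally whole exons
#' are deleted per taxon (gap runs) or in every taxon (all-row gap runs,
#' split condition ii). Because the only indels are whole-exon deletions,
#' the rows pad into a consistent alignment of gene length in which intron
#' columns hold the mask symbol in the reference row and gaps in every
#' transcript row.
#'
#' @param spec a [fixtureSpec()].
#' @param genomeFx result of [simGenome()].
#' @param seed integer seed.
#' @param dir optional directory to write one aligned FASTA per gene.
#' @param referenceRowId name of the masked genome row, default
#'   `"REF_genome"`.
#' @return list with `alignments` (named list of
#'   [LocusAlignment-class]), and `truth` (list per gene: `intronCols`
#'   0-based half-open matrix, `deletedExons` data.frame taxon/exon_index).
#' @export
simOrthologAlignments <- function(spec, genomeFx, seed, dir = NULL,
                                  referenceRowId = "REF_genome") {
  stopifnot(inherits(spec, "fixtureSpec"))
  genome <- Biostrings::readDNAStringSet(genomeFx$fasta)
  models <- parseGeneModels(genomeFx$gff)
  alignments <- list()
  truth <- list()
  for (gid in names(models)) {
    masked <- maskGene(genome, models[[gid]])
    refChars <- strsplit(masked$sequence, "", fixed = TRUE)[[1L]]
    L <- length(refChars)
    exonCols <- which(refChars != "#")
    spans <- genomeFx$geneLocal[genomeFx$geneLocal$gene_id == gid, ,
                                drop = FALSE]
    rows <- withSeed(substreamSeed(seed, paste0("aln|", gid)), {
      sharedDel <- stats::runif(nrow(spans)) < spec$sharedDelProb
      out <- list()
      for (tx in spec$taxa) {
        chars <- rep("-", L)
        chars[exonCols] <- refChars[exonCols]
        nSub <- stats::rbinom(1L, length(exonCols), spec$subProb)
        if (nSub > 0L) {
          # substitute in the transcript frame, never creating a stop
          # codon (the emulated transcripts are under coding constraint)
          splicedTx <- chars[exonCols]
          at <- sample(seq_along(splicedTx), nSub)
          for (k in at) {
            alts <- sample(setdiff(NUC_STATES, splicedTx[k]))
            ci <- (k - 1L) %/% 3L
            cpos <- ci * 3L + 1:3
            for (b in alts) {
              if (cpos[3L] > length(splicedTx)) { splicedTx[k] <- b; break }
              cand <- splicedTx[cpos]
              cand[k - ci * 3L] <- b
              if (!(paste0(cand, collapse = "") %in% STOP_CODONS)) {
                splicedTx[k] <- b
                break
              }
            }
          }
          chars[exonCols] <- splicedTx
        }
        del <- sharedDel | (stats::runif(nrow(spans)) < spec$exonDelProb)
        for (i in which(del)) {
          chars[spans$start[i]:spans$end[i]] <- "-"
        }
        out[[tx]] <- list(row = paste0(chars, collapse = ""),
                          deleted = spans$exon_index[del])
      }
      out
    })
    seqs <- c(setNames(vapply(rows, `[[`, "", "row"), names(rows)),
              setNames(masked$sequence, referenceRowId))
    aln <- LocusAlignment(gid, seqs, referenceRowId = referenceRowId)
    alignments[[gid]] <- aln
    delDf <- do.call(rbind, lapply(names(rows), function(tx) {
      d <- rows[[tx]]$deleted
      if (!length(d)) return(NULL)
      data.frame(taxon = tx, exon_index = d, stringsAsFactors = FALSE)
    }))
    truth[[gid]] <- list(
      intronCols = cbind(start0 = IRanges::start(masked$intronRuns) - 1L,
                         end0 = IRanges::end(masked$intronRuns)),
      exonSpans = spans,
      deletedExons = delDf %||% data.frame(taxon = character(),
                                           exon_index = integer()))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      Biostrings::writeXStringSet(aln@seqs,
                                  file.path(dir, paste0(gid, ".fasta")))
    }
  }
  list(alignments = alignments, truth = truth)
}

#' Ladder species tree over the fixture taxa
#'
#' Two clade-ladders joined at the root, matching the clade assignment of
#' [fixtureSpec()].
#'
#' @param spec a [fixtureSpec()].
#' @return an [ape::phylo].
#' @export
simSpeciesTree <- function(spec) {
  ladder <- function(taxa) {
    if (length(taxa) == 1L) return(taxa)
    paste0("(", taxa[1L], ",", ladder(taxa[-1L]), ")")
  }
  c1 <- names(spec$cladeMap)[spec$cladeMap == "clade1"]
  c2 <- names(spec$cladeMap)[spec$cladeMap == "clade2"]
  ape::read.tree(text = paste0("(", ladder(c1), ",", ladder(c2), ");"))
}

#' Simulate homolog gene trees with planted duplications
#'
#' Each gene tree starts as the species tree; for every branch of the
#' duplication plan, with the planned probability the entire clade below
#' that branch is replaced by a cherry of two copies of itself (a
#' concordant duplication). Tip labels are `taxon@geneNNN_copy`.
#'
#' @param spec a [fixtureSpec()] (its `dupPlan` names species-tree branch
#'   ids as produced by [branchPercentages()], i.e. sorted clade taxa
#'   comma-collapsed).
#' @param speciesTree [ape::phylo], usually [simSpeciesTree()].
#' @param seed integer seed.
#' @param nTrees number of gene trees, default `spec$nGenes`.
#' @param dir optional directory to write one Newick file per gene.
#' @return list with `trees` (named list of [ape::phylo]) and `truth`
#'   (data.frame gene, branch, duplicated).
#' @export
simHomologTrees <- function(spec, speciesTree, seed,
                            nTrees = spec$nGenes, dir = NULL) {
  stopifnot(inherits(spec, "fixtureSpec"))
  ids <- speciesBranchIds(speciesTree)
  plan <- spec$dupPlan
  if (length(plan)) {
    unknown <- setdiff(names(plan), ids)
    if (length(unknown))
      stop("duplication plan names unknown branches: ",
           paste(unknown, collapse = "; "))
  }
  trees <- list()
  truthRows <- list()
  for (g in seq_len(nTrees)) {
    gene <- sprintf("gene%03d", g)
    node <- asTreeNode(speciesTree)
    withSeed(substreamSeed(seed, paste0("tree|", gene)), {
      for (br in names(plan)) {
        if (stats::runif(1L) >= plan[[br]]) next
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          gene = gene, branch = br, stringsAsFactors = FALSE)
        brTaxa <- strsplit(br, ",", fixed = TRUE)[[1L]]
        node <- duplicateClade(node, brTaxa)
      }
    })
    # tip labels during simulation are "taxon" or "taxon|<copy path>";
    # rewrite them as taxon@geneNNN<copytag>
    finish <- function(n) {
      if (nodeIsTip(n)) {
        parts <- strsplit(n$label, "|", fixed = TRUE)[[1L]]
        tag <- if (length(parts) > 1L)
          paste(parts[-1L], collapse = "") else "a"
        n$label <- paste0(parts[1L], "@", gene, tag)
        return(n)
      }
      n$children <- lapply(n$children, finish)
      n
    }
    trees[[gene]] <- asPhylo(finish(node))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      ape::write.tree(trees[[gene]], file.path(dir, paste0(gene, ".tre")))
    }
  }
  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(gene = character(), branch = character())
  list(trees = trees, truth = truth)
}

# replace every clade whose taxon set equals `taxa` by a cherry of two
# copies of itself; copy tags accumulate on the tip labels after "|"
duplicateClade <- function(node, taxa) {
  addTag <- function(n, tag) {
    if (nodeIsTip(n)) {
      n$label <- paste0(n$label, "|", tag)
      return(n)
    }
    n$children <- lapply(n$children, addTag, tag = tag)
    n
  }
  rec <- function(n) {
    if (setequal(taxonOf(sub("\\|.*$", "", nodeTips(n))), taxa)) {
      return(newNode(list(addTag(n, "a"), addTag(n, "b"))))
    }
    if (!nodeIsTip(n)) n$children <- lapply(n$children, rec)
    n
  }
  rec(node)
}
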