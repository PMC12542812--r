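# baitCarver

Exon carving and tiled bait design from ortholog alignments, with the
gene-tree procedures needed to keep the resulting loci orthologous.

## The problem

Target-enrichment ("Hyb-Seq") studies of plant groups with large,
polyploid genomes need a custom set of capture baits: a few hundred to a
thousand low-copy nuclear loci, long enough to carry phylogenetic signal
but free of intron breakpoints that cause chimeric assemblies. Given

* per-ortholog multiple sequence alignments built from transcriptomes,
* one annotated reference genome (GFF3 + FASTA), and
* homolog gene trees for the same gene set,

`baitCarver` derives intron positions by subtracting annotated exons from
genes, inserts the intron-masked reference into each alignment, carves the
alignments into **complete exons**, filters the exons through a quantified
cascade, screens out gene families that are expanded in designated diploid
reference taxa, and emits 120-nt probes tiled at 2×. It also implements
the tree-side operations used to curate orthologs downstream of capture:
low-support branch collapsing, same-taxon tip masking,
monophyletic-outgroup (MO) ortholog pruning, missing-data column trimming,
rooted orthogroup extraction and concordant gene-duplication mapping onto
a species tree. It is aimed at phylogenomics groups designing clade-
specific kits and at anyone re-running such a design reproducibly.

## The method in brief

An alignment column is split-eligible when (i) the masked genomic
reference marks it as intronic, or (ii) all transcriptome rows are gapped
there; maximal runs of such columns separate the complete exon blocks.
Each block is then pushed through the cascade (comparison directions are
part of the contract):

| stage | rule |
|---|---|
| length, pass 1 | keep blocks **> 700** columns |
| informativeness | keep blocks with PIS proportion **> 0.02**, where a column is parsimony-informative iff ≥ 2 nucleotide states each occur in ≥ 2 sequences |
| row gap screen | remove *sequences* with gap proportion **> 0.5**, then re-evaluate |
| length / identity / occupancy, pass 2 | keep blocks **≥ 800** columns, mean pairwise identity **≥ 75 %** (pair-gapped columns excluded), **≥ 10** sequences |
| stop-codon screen | reject blocks with an internal stop codon in the best of the three reading frames; reject mean gap ratio > 0.25 |
| clade coverage | require representatives of both major clades |

Loci whose homolog tree shows more than **3 duplications** (copy count − 1)
in either diploid reference taxon are removed. From the survivors a
kit-sized random subset is drawn; per clade the sequence with the fewest
gaps represents the locus, and probes of 120 nt are tiled every 60 nt with
a flush-end probe, giving `floor((L−120)/60) + 1 + [(L−120) mod 60 ≠ 0]`
probes on an ungapped target of length L.

MO pruning roots each gene tree on its (required monophyletic,
non-repeating) outgroup and walks root→tips, discarding the smaller child
of every node whose children share a taxon; orthologs are emitted with
≥ 15 ingroup taxa. Duplication mapping calls a node concordant when both
child clades have the same species-tree MRCA, assigns it to that branch,
and reports per-branch percentages over the orthogroups able to witness
each branch.

All inputs can be simulated with known ground truth (`fixtureSpec()`,
`simGenome()`, `simOrthologAlignments()`, `simHomologTrees()`), which is
how the test suite and the acceptance script exercise the whole workflow
offline.

## Worked example

```r
library(baitCarver)

spec <- fixtureSpec(nGenes = 30, nTaxa = 20)
fx   <- simGenome(spec, seed = 7, dir = tempfile())
al   <- simOrthologAlignments(spec, fx, seed = 7)
st   <- simSpeciesTree(spec)
ht   <- simHomologTrees(spec, st, seed = 7, nTrees = 30)

res <- runBaitPipeline(al$alignments, spec$cladeMap, designThresholds(),
                       seed = 11, homologTrees = ht$trees,
                       referenceTaxa = c("taxon05", "taxon20"),
                       kitSize = 5)
length(res$blocks)      # 104 carved exons
length(res$survivors)   # 33 pass the cascade
res$design$probeSet
#> ProbeSet: 150 probes over 5 loci, 4613 target bp
res$design$report[, c("n_loci", "n_genes", "locus_len_mean",
                      "total_target_bp", "total_reference_bp")]
#>   n_loci n_genes locus_len_mean total_target_bp total_reference_bp
#> 1      5       5          922.6            4613               9226
```

The 30 simulated genes yield 104 complete exons; 33 survive the cascade
and the duplication screen, 5 are drawn for the toy kit. Each kit locus is
represented once per clade (hence reference bp = 2 × target bp), and 2×
tiling places 150 probes over 4,613 target bases (~1.95 probes per base).
`res$ledger` records every measurement, threshold and verdict per locus,
so any rejection can be audited.

A thin command-line wrapper with the same steps as subcommands lives in
`inst/scripts/baitcarver.R` (`simulate`, `mask-introns`, `carve`,
`filter`, `screen-dups`, `design`, `mo-prune`, `map-dups`).

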