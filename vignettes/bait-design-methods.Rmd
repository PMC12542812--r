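---
title: "Designing exon-based bait kits from ortholog alignments: methods and choices"
author: "baitCarver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing exon-based bait kits from ortholog alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitCarver)
```

## Why carve exons?

Target-enrichment kits for polyploid plant lineages fail in a
characteristic way: when a targeted locus spans several exons, assemblers
may stitch exons from *different* gene copies into one chimeric contig,
and every downstream orthology inference inherits the error. The design
strategy implemented here avoids that failure mode by targeting **single
complete exons**: intron positions are identified on one annotated
reference genome, transferred into transcript-derived ortholog alignments
through an intron-masked reference row, and the alignments are cut at
those positions. Long exons are then preferred, because a locus
contributes one gene tree regardless of its length, while short loci have
higher gene-tree error.

## Interval model and intron masking

A gene model is a gene interval plus the union of its annotated exon
intervals, merged over transcripts into non-overlapping runs (the union
is the conservative, deterministic reading when several transcripts
exist). Introns are the set complement of the exons inside the gene; the
complement is computed with `IRanges`, the interval algebra every
Bioconductor workflow uses, rather than ad hoc arithmetic. Internally the
package therefore stores intervals in the native 1-based closed
convention of `IRanges`; the exported intron table uses 0-based half-open
coordinates, which is the convention of interval exchange formats, so the
conversion happens exactly once at the I/O boundary.

Masked genes are emitted in transcribed orientation (minus-strand genes
are reverse-complemented first, then their mirrored intron runs are
masked), because the alignments the mask is inserted into are alignments
of transcripts. The mask symbol defaults to `#`: it must be a single
character distinct from the nucleotide alphabet, `N` and the gap `-`, so
that split condition (i) below is an exact character test rather than a
heuristic.

## Split conditions and their reading

An alignment column is a split point when

* **(i)** the masked reference marks it as intronic, or
* **(ii)** the transcriptome rows are gapped there.

Condition (ii) is not quantified in words alone, so the package freezes
the strictest reading that can never split inside a sequenced exon: *all*
non-reference rows must be gapped, and the maximal all-gap run must reach
a configurable minimum length (`minSharedGapRun`, default 1 column). A
`gapFraction` knob (default 1.0) exposes the laxer "a fraction of rows"
readings without making them the default. Runs from (i) and (ii) are
OR-ed per column and merged; the complement of the merged runs becomes
the exon blocks. Exon length is defined as the block's column count
(including internal gap columns) because every later filter operates on
alignments, and a single deterministic length definition is needed.

Degenerate inputs behave predictably: an all-intron reference yields zero
blocks; a block in which a row is entirely gaps drops that row (it
carries no data for that exon); carving a carved block again returns it
unchanged.

## The filtering cascade

`designThresholds()` carries every numeric gate; the defaults are the
published design conditions of the workflow this package implements, and
their comparison directions are part of the contract (each one is frozen
by a test):

* pass-1 length: keep blocks strictly longer than **700** columns;
* informativeness: parsimony-informative proportion strictly greater
  than **0.02**. A column is informative iff at least two unambiguous
  nucleotide states each occur in at least two sequences; gaps and
  ambiguity codes (all treated as `N`) carry no state;
* row gap screen: remove *sequences* whose gap proportion strictly
  exceeds **0.5** — the screen removes rows, not loci, and the block is
  re-evaluated afterwards, which is why a 10-row block can die at the
  occupancy gate after losing one gappy row;
* pass-2: length **≥ 800**, at least **10** sequences, mean pairwise
  identity **≥ 75 %**. Identity of a pair excludes columns gapped in
  either member; pairs with no comparable columns are skipped and the
  mean over pairs is unweighted. This definition is frozen here because
  interactive alignment viewers do not document theirs;
* stop-codon screen: for each of the three frames the internal stops
  (TAA/TAG/TGA, ignoring a stop in a row's final complete codon) are
  counted on the ungapped rows; the frame minimising the total is chosen
  and the block is rejected if any row still carries an internal stop.
  The companion "excessive gaps" criterion of the original manual review
  is unquantified, so it is operationalised as a deterministic proxy: an
  all-row mean gap ratio above **0.25** rejects the block, and the
  proxy's value is recorded in the ledger like every other measurement;
* clade coverage: each clade label of the clade map must be represented,
  so the kit captures equally well across the major lineages.

Every stage writes `(locus, stage, metric, value, threshold, verdict)` to
a filter ledger, and a locus rejected at stage *k* has no entries past
*k*. The ledger is the audit trail that makes the design reproducible.

## Duplication screen

Copy numbers are counted per taxon in each homolog gene tree
(`taxon@sequenceID` tips). "Duplications" are copy count − 1, so a
reference taxon with four copies shows three duplications and is kept
under the default ceiling of **3**, while five copies are removed — the
boundary pair that freezes the counting convention. The reference taxa
are configurable (any diploids known to lack a whole-genome duplication);
loci whose gene has no homolog tree are dropped by default, since absence
of a tree is not evidence of low copy number.

## Kit subset, representatives and tiling

The kit subset is a uniform draw without replacement; representative
selection takes, per clade, the sequence with the fewest gap characters,
breaking ties uniformly at random. Both draws consume per-purpose random
streams derived by hashing `(seed, locus id)` into a 31-bit substream
seed, so results do not depend on the order in which loci are processed
and a single integer seed reproduces the entire kit byte for byte.

Representatives are exported ungapped — probes are synthesised molecules
and alignment gaps are artifacts. Tiling at 2× starts a 120-nt probe
every 60 nt and adds a flush-end probe at `L − 120` when the regular grid
misses the 3′ end, so terminal bases are covered; the probe count obeys
`floor((L−120)/60) + 1 + [(L−120) mod 60 ≠ 0]`. Probes containing `N`
are dropped and counted (configurable), mirroring common vendor
behaviour without claiming to reproduce any vendor's proprietary QC —
which is also why no attempt is made to reproduce a vendor-reported
probe total.

## Tree-side operations

*Support collapsing* contracts internal branches with support strictly
below 70 into polytomies; unlabeled branches are never collapsed and the
supports of removed branches are discarded (contraction semantics).

*Tip masking* removes redundant same-taxon tips, keeping the tip with the
most unambiguous characters (tie → lexicographically smallest sequence
id). Two rules run to a fixpoint: same-taxon sister tips, and a tip whose
parent's sister is a same-taxon tip — together they reduce monophyletic
and paraphyletic same-taxon groups to a single representative. Character
count (not branch length) is the keep criterion; that choice is frozen
here because sources differ.

*MO pruning* requires non-repeating, monophyletic outgroup tips, roots on
the outgroup, and discards the smaller child of every duplication node on
a root-to-tip walk. Equal-sized children are resolved against the
lexicographic order of their sorted tip labels — the source algorithm
leaves ties unspecified and a reproducible kit needs determinism. Trees
failing outgroup monophyly are rejected with a reason code rather than
repaired. Orthologs are emitted with at least 15 ingroup taxa.

*Column trimming* removes columns with strictly more than 70 % missing
data (gap or `N`), preserving row order; trimming everything returns an
empty alignment with a warning rather than an error.

*Orthogroup extraction* takes the homolog tree **as rooted**: the
presence of at least one outgroup tip anywhere vouches for the upstream
rooting, and the maximal all-ingroup subtrees with ≥ 10 distinct taxa are
returned. Re-rooting on the outgroup here would merge ingroup clades
that the original rooted topology keeps separate, so it is deliberately
not done; an unrooted tree without outgroup evidence is rejected. A
duplication node is *concordant* when both child clades have the same
species-tree MRCA; it is mapped to that node's subtending branch, and
polytomous or discordant duplication nodes are counted but not mapped.
Terminal branches can receive duplications (taxon-specific expansions).
The per-branch percentage divides the orthogroups with a duplication
mapped to the branch by the orthogroups *able to witness* it — those
whose taxa reach at least two child subtrees of the branch's node (or
contain the taxon, for a terminal branch). Branches witnessed by no
orthogroup report `NA`, never 0. The witness denominator is this
package's definition; published per-branch percentages computed with
undocumented denominators are therefore not claimed to be reproduced
number for number.

## What the synthetic study systems emulate

The generator (`fixtureSpec()` and the `sim*()` functions) produces a
single-contig genome whose genes have known exon/intron structure,
spliced transcripts evolved independently per taxon, and homolog trees
with duplications planted on chosen species-tree branches. Defaults are
chosen once to reflect the study conditions the thresholds were written
for: 29 taxa in two major clades, exon lengths 120–1100 bp spanning the
700/800-bp gates, introns 60–400 bp, a per-site substitution probability
of 0.03 (keeping within-dataset identity well above the 75 % gate, as in
a family-level transcriptome panel), and a 5 % chance per taxon and exon
of whole-exon loss. Transcripts are built from non-stop codons and
substitutions are re-drawn when they would create an in-frame stop, so
fixtures are codon-clean by construction — the stop-codon screen then
tests real violations, not simulation noise.

Two features of real data are deliberately *not* emulated: small indels
(the only indels are whole-exon deletions, so alignments are exact by
construction and condition (ii) can be planted precisely), and
transition/transversion or rate heterogeneity (uniform per-site
substitution suffices to exercise thresholds). Consequently, passing
tests demonstrate the correctness of the interval algebra, the carving
rules, the statistics and the tree operations — not robustness to
alignment error, which in practice is delegated to the external aligners
that produce this package's inputs.

Duplications are planted by doubling the entire clade below a branch, so
planted events are always species-tree-concordant; discordant mapping is
exercised with hand-built trees instead.

## Numerical and size choices

All statistics are exact integer/rational computations; the only
floating-point comparisons are the threshold gates themselves, applied to
values (proportions, percentages) computed from counts. Random draws in
package code always flow through seeded substreams; nothing reads the
global RNG state implicitly. The test suite checks each statistic against
an independent brute-force implementation on hundreds of random
alignments, recovers planted exon boundaries on a 100-gene fixture at
substitution rate 0.02, prunes 500 random planted-duplication trees
against an enumeration oracle, and verifies the tiling closed form for
every length from 120 to 3000 nt. The acceptance script runs the full
pipeline on 120 genes × 29 taxa and the duplication mapping on 200
orthogroups — sizes chosen so the whole design remains a desk-scale,
single-CPU computation while every stage still processes hundreds of
objects.

## Known limitations

* Alignment and re-alignment are out of scope; the package consumes
  aligned inputs and its fixtures are alignment-exact by construction.
* The stop-codon screen assumes one reading frame per block (a carved
  complete exon); blocks spanning frame shifts would need codon-aware
  preprocessing.
* MO pruning inherits the known bias of the MO family of algorithms
  under allopolyploidy: pruning the smaller duplication child can
  preferentially discard one subgenome.
* The kit-size subset is uniform; no optimisation (e.g., for GC content
  or probe thermodynamics) is attempted, and vendor probe QC is not
  modelled.
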