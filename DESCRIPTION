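Package: baitCarver
Title: Exon Carving and Tiled Bait Design from Ortholog Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for designing taxon-specific target-enrichment bait
    sets from transcriptome-derived ortholog alignments and one annotated
    reference genome. Intron positions are derived by subtracting annotated
    exons from genes, the intron-masked reference row is used to carve
    complete exon sub-alignments out of each ortholog alignment, and carved
    exons are passed through a quantified filtering cascade (length,
    parsimony-informative sites, per-sequence gap ratio, mean pairwise
    identity, sequence occupancy, stop-codon screen, clade coverage). Loci
    whose homolog gene trees show gene-family expansion in designated
    diploid reference taxa are removed before per-clade representative
    selection and emission of tiled 120-nt probes. The package also
    implements the tree-side procedures used for ortholog curation:
    low-support branch collapsing, same-taxon tip masking,
    monophyletic-outgroup (MO) ortholog pruning, missing-data column
    trimming, rooted orthogroup extraction, and concordant gene-duplication
    mapping onto a species tree. A synthetic fixture generator produces
    genomes, annotations, alignments and gene trees with known ground truth
    so the whole workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
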