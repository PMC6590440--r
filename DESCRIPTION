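Package: plastevol
Title: Comparative Evolution of Plastid Genome Structure, Content and
    Substitution Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid genomes (plastomes):
    reading annotated plastomes from GenBank flat files, detecting the large
    two-copy repeat and classifying its orientation (inverted vs direct),
    partitioning the quadripartite genome and computing per-region
    statistics; scoring gene and intron content (intact, pseudogene, absent)
    and mapping losses onto a fixed phylogeny by weighted (Sankoff)
    parsimony; representing genomes as signed gene orders, computing exact
    signed reversal distances and explicit minimal inversion scenarios with
    repeat-orientation bookkeeping, and placing inversions on a tree;
    estimating per-branch synonymous divergence under an MG94xF3x4 codon
    model and total divergence under GTR+Gamma+I, with repeat versus
    single-copy rate comparisons; and a simulator that generates plastomes,
    inversion and loss histories, and sequence alignments with
    copy-correction (gene conversion) between repeat copies, providing
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'plastome-io.R'
    'content.R'
    'lycophyte-data.R'
    'rates.R'
    'rearrangement.R'
    'simulate.R'
    'structure.R'
    'utils.R'
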