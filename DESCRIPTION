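Package: caspevo
Title: Comparative Evolutionary Analysis of the Caspase-1 Gene Locus
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the evolutionary history of a
    multi-gene inflammatory caspase locus across mammal species: synteny-aware
    exon annotation from locus sequences, four-way gene status calls
    (present, partial in-frame, pseudogene, absent) with lesion evidence,
    detection of segmental duplication and gene-conversion tracts, Dollo
    parsimony gain/loss reconstruction on a species tree, recombination-aware
    counting-based (Nei-Gojobori/SLAC-style) selection scans, aspartate
    self-cleavage-site conservation reports, and conservation-based
    classification of inbred-strain missense variants. A codon-level locus
    evolution simulator with a complete truth log supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, SequenceMatching, Alignment
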