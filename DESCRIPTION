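Package: tetrap
Title: Transposable-Element Activation, Antisense Traps and Endogenous
    siRNA Signatures During Global Demethylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies transposable-element (TE) activation and its
    silencing correlates in induced global-demethylation time courses
    (Dnmt1 conditional knockout-style designs in mouse embryonic stem
    cells). Implements TE-class expression summaries with length- and
    library-normalised log2 RPM values and Z-score matrices, a per-gene
    exact binomial test for pervasive antisense "trap" transcription
    against a globally estimated antisense proportion, whole-genome
    bisulfite methylation quantitation in 50-CpG windows and over
    features and TE classes, endogenous siRNA signature analysis
    (length/strand distributions, 5' nucleotide composition, 5'-5'
    overlap signatures, consensus coverage profiles), and ChIP 1-kb tile
    log2 observed/expected enrichment with TE-class fold-change calls.
    A calibrated synthetic-data generator emulates the demethylation
    time course so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
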