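Package: gokuphage
Title: Discovery, Excision and Integration Modelling of dif-Flanked Gokushovirus Prophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting gokushovirus (Microviridae, Gokushovirinae)
    prophages that integrate into bacterial chromosomes at the 28-bp XerC/XerD
    dif site. Implements capsid-homology locus finding, attachment-site direct
    repeat boundary detection, dif-site grammar classification (11-bp XerC arm,
    6-bp spacer, 11-bp XerD arm), excision of circular replicative-form phage
    genomes, a model of XerC/XerD-dependent integration, position-weight-matrix
    iterative scanning of metagenome-assembled phage genomes for dif-like
    motifs with coding-context filtering, rotation-aware average nucleotide
    identity and clade clustering, per-column alignment identity profiles, and
    in-silico PCR diagnostics. Ships a seeded synthetic-genome generator that
    emulates the enterobacterial prophage architecture together with a
    ground-truth oracle for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
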