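Package: metafam
Title: Gene Family Abundance Estimation and Benchmarking for Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end framework for estimating and benchmarking protein
    family abundance from shotgun metagenomes. Builds in silico mock
    communities from annotated reference genomes, simulates error-prone
    shotgun reads with known truth, translates reads into candidate peptides
    by six-frame translation with stop-codon splitting and length filtering,
    classifies peptides into protein families by local homology search under
    read-length specific bit-score thresholds, and estimates gene-length
    normalized family relative abundance by count- or coverage-based metrics.
    Evaluation utilities quantify annotation accuracy (L1 profile error,
    threshold sweeps, empirical false-positive rates), sequencing-depth
    behaviour (rarefaction, bootstrap coefficients of variation, library-size
    calculators) and functional alpha/beta diversity. A comparison layer
    provides per-family rank-based association tests with Storey q-values,
    pathway enrichment, ordination and permutational MANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
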