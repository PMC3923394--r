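Package: chipscape
Title: Simulation and Downstream Analysis of Transcription-Factor ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the downstream analysis of
    transcription-factor ChIP-seq experiments in compact plant genomes:
    strand-aware read extension to fragment length, fixed-width window
    coverage, a Poisson sample-versus-input enrichment caller, genic-zone
    peak annotation (promoter / gene body / downstream), metagene average
    binding profiles over 100 segments with per-gene maximum normalization,
    degenerate IUPAC consensus-motif frequency statistics against a
    GC-composition null, and hypergeometric functional-category
    over-representation. A seeded simulator generates miniature genomes,
    gene models, planted binding sites and ChIP/input read sets so the whole
    pipeline can be exercised and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    readr,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
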