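Package: crmkit
Title: Classification and Spike-In Quantification of HDAC-Bound Cis-Regulatory Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for post-alignment analysis of histone
    deacetylase ChIP-seq experiments in early vertebrate embryos.
    Classifies bound cis-regulatory modules (CRMs) by their histone-mark
    context (H3K27ac/H3K27me3 Venn partition), quantifies spike-in
    (ChIP-Rx) normalized pan-H3K acetylation changes between germ layers
    and HDAC-inhibited conditions, assigns CRMs to nearest genes and
    gene classes, filters strictly zygotic transcripts from TPM time
    courses, categorizes genes by germ-layer expression, and provides
    the accompanying inferential toolkit (Welch t, Cohen's d, one-sided
    Fisher exact, qPCR percent input with error propagation). A
    synthetic-data generator with known ground truth emulates the full
    experimental design for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
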