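Package: markwise
Title: Integrative Histone-Mark and Expression Analysis with Super-Enhancer Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for linking differential gene expression
    with differential histone-mark occupancy in two-condition studies. Provides a
    negative-binomial Wald test for count matrices, TSS-window aggregation of
    ChIP-seq signal for the marks H3K4me3, H3K4me1, H3K27ac and H3K27me3,
    congruence classification of expression and occupancy changes, rank-ordering
    of stitched enhancers (ROSE-style) with an elbow cutoff for super-enhancer
    calling, position-weight-matrix motif scanning at a relative-score threshold,
    gene-set enrichment (running-sum ES with permutation NES/FDR), hypergeometric
    over-representation, a simplified upstream-regulator activation z-score,
    4C viewpoint interaction profiling with power-law distance-decay background,
    3C relative interaction frequencies, ChIP-qPCR percent-input quantification,
    and a seeded synthetic-data generator that plants all of the structures the
    pipeline is designed to recover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
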