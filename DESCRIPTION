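Package: lentitox
Title: Multi-Omic Genotoxicity Assessment of Lentiviral Vector Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis toolkit for assessing the genotoxic
    potential of lentiviral gene-therapy vectors from multi-omic read-outs.
    Starting from mapped vector integration sites with sheared-fragment
    sequence counts, gene-level expression count matrices and methylation
    beta values, the package annotates integration sites against gene
    models, detects common integration sites by genomic linkage
    clustering, tracks clonal expansion through sequence-count changes,
    calls differentially expressed genes with empirical-Bayes moderated
    t-statistics, performs hypergeometric over-representation and ranked
    gene-set enrichment, derives and scores cancer gene signatures,
    builds weighted co-expression networks with topological-overlap
    modules, calls differentially methylated positions by delta-beta
    thresholding, and integrates all layers into a per-condition
    genotoxicity report. A fully seeded synthetic-data generator emulates
    the complete study design for calibration and testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
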