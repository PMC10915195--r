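Package: ssgwas
Title: Single-Step GBLUP SNP-Window Association and Pathway Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end single-step genomic BLUP (ssGBLUP) association pipeline for
    repeated multi-trait records: pedigree and genomic relationship matrices with
    blending and scaling, multi-trait repeatability-model REML (EM with
    average-information acceleration), back-solution of per-SNP additive variances
    from genomic breeding values, aggregation into overlapping and non-overlapping
    SNP windows of several sizes with per-size selection thresholds, SNP-to-gene
    distance-bin mapping, two-sided hypergeometric pathway enrichment with
    step-down multiple-testing correction, and pairwise comparison of window
    schemes by shared pathways and genes. Includes a simulator for pedigrees,
    gene-drop genotypes and correlated repeated phenotypes so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
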