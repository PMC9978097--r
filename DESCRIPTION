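Package: mrflow
Title: Two-Sample Mendelian Randomization Workflows for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian randomization
    (MR) from GWAS summary statistics. Covers instrument selection (p-value
    screening, greedy linkage-disequilibrium clumping, variance-explained and
    F-statistic strength filters), allele harmonization with palindromic-SNP
    resolution, five causal estimators (fixed- and random-effects
    inverse-variance weighted, maximum likelihood, MR-Egger, weighted median,
    weighted mode), a sensitivity suite (Cochran's Q heterogeneity, Egger
    intercept pleiotropy test, MR-PRESSO global/outlier/distortion tests,
    leave-one-out), Benjamini-Hochberg false-discovery-rate calling across
    exposure families, and bidirectional plus replication passes. A seeded
    generator of synthetic two-sample GWAS summary statistics with known
    causal truth makes the whole chain verifiable without external downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
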