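Package: psagwas
Title: Prioritized Subset Analysis for Case-Control Genome-Wide
    Association Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Case-control genome-wide association analysis with
    knowledge-driven multiple-testing control. Provides genotype quality
    control (minor-allele frequency and exact Hardy-Weinberg filters),
    per-SNP allelic chi-square association tests, partitioning of SNPs
    into prioritized and non-prioritized subsets by window overlap with
    candidate genes and linkage markers, stratified false discovery rate
    control with Storey-Tibshirani smoothing-spline pi0 estimation,
    permutation-based FDR verification, and a synthetic case-control
    genotype simulator for power studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
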