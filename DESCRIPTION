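Package: tamsig
Title: Proliferating Tumor-Associated Macrophage Signatures and Immune-Context
    Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for proliferating (PCNA+) tumor-associated
    macrophages in breast cancer expression cohorts: differential expression of
    M1/M2 macrophage polarization gene panels between high and low PCNA+ TAM
    groups with Fisher-exact enrichment, a summed cytotoxic T-cell / MHC class
    II (Tc/ClassII) immune-context score with median dichotomization, a
    resampling-vote plus non-negative-least-squares gene surrogate for PCNA+
    TAM counts with Youden-threshold classification and repeated stratified
    cross-validation, and recurrence-free-survival stratification by the joint
    high-TAM / low-immune-score risk group (Kaplan-Meier, log-rank, Cox
    proportional hazards). Includes a synthetic-cohort generator with the
    statistical structure the analysis assumes, so every stage is testable
    without external data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
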