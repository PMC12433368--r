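Package: hemoscreen
Title: Globin-Chain Ratio Screening for Newborn Hemoglobinopathies from
    Targeted Mass-Spectrometry Peak Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for newborn hemoglobinopathy screening from
    targeted (parallel-reaction-monitoring) mass-spectrometry peak areas of
    globin-chain proteo-specific tryptic peptides. Computes peptide
    concentrations against stable-isotope-labeled internal standards,
    dimensionless globin-chain ratios and mutant-to-wild-type variant ratios
    with signal-to-noise detection filtering; evaluates and refits binary
    logistic risk models for alpha- and beta-thalassemia; performs ROC, AUC
    and Youden-index cutoff optimization; applies a screening cutoff table to
    produce per-sample calls; and summarizes clinical (confusion-matrix) and
    assay-validation (CV, carryover, matrix effect, recovery, stability)
    performance. Includes a genotype-stratified synthetic cohort generator so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    tidyr,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
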