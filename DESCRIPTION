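Package: predscreen
Title: Family-Wise-Error-Gated Screening and Discriminant Validation of
    Predator-Induced Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening pipeline for cross-species microarray studies of
    predator-induced phenotypic plasticity. Implements exact Sidak family-wise
    error control with per-probe one-way ANOVA, canonical linear discriminant
    analysis fitted from scratch (coefficients, centroids, percent
    discrimination, territorial-map boundary lines, nearest-centroid
    classification), multi-method hierarchical cluster validation
    (single/average linkage with Euclidean distance, Ward with squared
    Euclidean), signed fold-change screening with a revert-to-control rule that
    labels genes as predator-common or predator-specific, and a synthetic-data
    generator reproducing the five-treatment-group, triplicate-chip study
    design including a plantable hybridization failure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests:
    MASS,
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
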