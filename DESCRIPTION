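Package: episcore
Title: DNA Methylation Scores for Plasma Protein Levels and Incident Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains sparse CpG-weight predictors (EpiScores) of circulating
    plasma protein levels from DNA-methylation beta-value matrices by
    elastic-net penalised regression with cross-validated penalty selection,
    after rank-based inverse normalisation and residualisation of protein
    levels on covariates and known protein quantitative trait loci (pQTLs).
    Validates and selects predictors by out-of-sample Pearson correlation,
    projects weight sets onto new methylation cohorts, and relates projected
    scores to incident disease through nested Cox proportional-hazards models
    with Efron tie handling, Benjamini-Hochberg false discovery rate control,
    Schoenfeld proportional-hazards diagnostics, follow-up truncation
    sensitivity analyses, and a logistic mode for binary outcomes. Includes a
    synthetic-cohort simulator with planted ground truth so the full pipeline
    is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    survival,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
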