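Package: clotlyse
Title: Turbidimetric Fibrin Clot Formation and Lysis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing fibrin clot turbidity assays and paired
    pre/post clinical cohorts. Extracts clot formation and lysis parameters
    (lag time, maximum absorbance, 50% and 100% lysis times, clot lysis
    area) from plate-reader absorbance time series, averages duplicate
    wells with quality-control flags, and runs the cohort-level workflow:
    normality-routed paired comparisons, chi-squared tests for dichotomous
    variables, repeated-measures correlation, and random-intercept linear
    mixed-model regression. A synthetic-data module generates turbidity
    curves with known ground truth and paired cohorts with configurable
    marginal moments and within-subject correlation structure, so the whole
    pipeline is testable without patient data. Includes serial-dilution
    arithmetic for assay reagent preparation and HbA1c unit conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
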