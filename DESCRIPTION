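Package: phenodiag
Title: Population-Level Diagnostics for Phenotype Algorithms on OMOP-Shaped Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates phenotype algorithms (computable cohort definitions)
    against patient-level observational data shaped like the OMOP Common Data
    Model. Loads and validates person, observation-period, clinical-event,
    visit and vocabulary tables; resolves concept sets over the concept
    hierarchy; instantiates declarative cohort definitions with inclusion-rule
    attrition; and computes population-level diagnostics: cohort counts,
    stratified incidence rates with person-time denominators, time
    distributions, index-event breakdown, visit context, cohort overlap,
    temporal characterization and standardized-mean-difference covariate
    balance. Results are assembled into a file-based, privacy-censored
    (minimum-cell-count) results model of plain CSV tables that can be merged
    across data sources for joint review. A synthetic-data generator with
    configurable demographics, disease-onset rates, coding lag and visit
    patterns provides a ground-truth-bearing test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
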