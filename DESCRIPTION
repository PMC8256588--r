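Package: eosmask
Title: Prevalence of Airway Eosinophilia from Quantitative Sputum Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the true prevalence of airway luminal
    eosinophilia from longitudinal quantitative sputum cytometry records.
    Classifies sputum samples as eosinophilic at configurable intact
    eosinophil-percentage thresholds augmented by semi-quantitative grading
    of free eosinophil granules (FEG), detects longitudinal re-emergence
    (unmasking) of eosinophilia with etiology attribution, composes staged
    prevalence estimates (intact-only, FEG-augmented, extrapolated total),
    fits a two-state discrete-time Markov chain over per-sample calls as a
    sensitivity analysis, and generates synthetic longitudinal cohorts with
    a latent eosinophilic state and corticosteroid/neutrophilia masking for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
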