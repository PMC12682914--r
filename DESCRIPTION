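Package: circaBP
Title: Circadian Blood-Pressure Phenotyping for Acute Stroke Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phenotyping circadian blood-pressure (BP) organization
    from high-frequency monitoring in the first 72 hours after acute ischemic
    stroke. Provides quality control and artifact editing for mixed
    invasive/oscillometric BP series, state-space (Kalman) imputation of short
    gaps, per-patient 24-hour cosinor regression (MESOR, amplitude, acrophase),
    nocturnal dipping classification, multiscale variability features,
    Gaussian-mixture phenotype clustering with bootstrap Jaccard stability
    assessment, and an outcome-association layer (contingency tests, calibration
    and collinearity diagnostics, effect sizes, Kaplan-Meier and adjusted
    logistic/Cox models). A synthetic cohort generator emulating the monitoring
    design of acute stroke units supplies fully labelled test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    dplyr,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    car,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
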