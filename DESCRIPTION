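Package: protontwin
Title: Digital-Twin Adaptive Proton SBRT Planning with Patient-Specific Setup Margins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital-twin workflow for adaptive two-fraction proton
    stereotactic body radiotherapy of the prostate. Predicts patient-specific
    clinical target volume (CTV) setup margins from geometric image features via
    Gaussian-process regression, emulates robustly optimized proton plans with a
    surrogate dose engine over the standard 21-scenario setup/range uncertainty
    space, scores candidate plans on each treatment fraction's anatomy with an
    adapted 12-function ProKnow system (dose-volume metrics, Paddick conformity,
    dose falloff), and selects the optimal plan per fraction. Includes a fully
    parameterized synthetic pelvic-cohort generator so every pipeline stage is
    testable without clinical imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
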