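Package: ventdose
Title: Estimate Minute Ventilation from Wearable Data and Compute Air
    Pollution Inhaled Dose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating minute ventilation (VE, L/min) from
    predictors that are easy to measure with wearable devices: heart rate,
    breath frequency, age, sex and forced vital capacity (FVC).  Provides
    closed-form power-function prediction models and six previously
    published comparison models, a log-log linear mixed-model pipeline
    with per-subject random intercepts and slopes for fitting such models
    to pooled per-minute physiological data, subject-grouped k-fold
    cross-validation with percent-error reporting, spirometry
    reference-equation support (GLI-style predicted FVC and
    percent-predicted classification), pollutant inhaled-dose integration
    on a one-minute grid, and a synthetic-data generator that reproduces
    the assumed statistical structure for testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
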