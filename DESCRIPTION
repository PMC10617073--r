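Package: strokemsm
Title: Continuous-Time Multistate Markov Models for Panel-Observed Stroke
    Functional Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a three-state continuous-time Markov model (good outcome,
    poor outcome, death, with recovery allowed) to panel-observed functional
    status data such as quarterly modified Rankin Scale follow-up of stroke
    patients. Transition intensities depend multiplicatively on baseline
    covariates; estimation maximises the panel-data likelihood built from
    matrix-exponential transition probabilities. Includes mean sojourn times,
    hazard ratios with Wald intervals, AIC and likelihood-ratio model
    comparison, observed-versus-expected prevalence diagnostics, expected
    survival curves, and a seeded synthetic cohort generator for validation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
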