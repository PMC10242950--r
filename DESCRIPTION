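Package: beastr
Title: Scoring, Simulation and Mixed-Model Inference for the Berlin
    Estimation Adjustment Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing social information use in the Berlin
    Estimation Adjustment Task (BEAST), a two-stage numerosity estimation
    task in which participants revise a first estimate after seeing a
    peer's estimate. Provides exact scoring of the adjustment weight
    s = (E2 - E1)/(X - E1), stay/copy/compromise strategy classification
    with round-validity and participant-exclusion rules, an agent-based
    synthetic cohort generator calibrated by moment matching to published
    group statistics, and the study's inference layer: random-intercept
    linear and logistic mixed models, Tukey-adjusted group contrasts,
    latent-scale intraclass correlation and Nakagawa marginal/conditional
    R-squared, and a one-way ANOVA of first-estimate accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    multcomp,
    pracma,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
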