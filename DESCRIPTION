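Package: vtdual
Title: Simulation and Analysis of Visuotactile Dual-Task Localization
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to simulate and analyse dual-task experiments combining
    a self-terminated visual search task with a spatial localization task
    delivered through visual, tactile, or redundant visuotactile cues.
    Provides a synthetic-observer generator for the seven-condition
    within-subject design (blocked cue schedules, eight-direction keypad
    responses, serial self-terminating search, per-trial gaze summaries),
    per-condition behavioural metrics (detection performance, localization
    accuracy, signed angular error and its variance, median search time and
    dual-task interference), the maximum-likelihood cue-integration
    benchmark for bimodal localization variance, and repeated-measures
    inference with Shapiro-Wilk normality gating, Mauchly sphericity
    diagnostics, Greenhouse-Geisser correction and Holm-Bonferroni
    post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
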