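Package: audcog
Title: Central Auditory Test Simulation and Longitudinal Cognitive Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether central auditory tests can track cognitive
    trajectories in longitudinal HIV cohorts. Provides virtual listeners with
    logistic psychometric functions; trial-by-trial simulators of four adaptive
    procedures (Bekesy-like pure-tone tracking, an adaptive gap-detection
    staircase, the Hearing in Noise Test, and a digit-triplet speech-in-noise
    test with paired maskers); an ex-Gaussian response-time model with
    maximum-likelihood fitting; visit-level cohort selection filters with an
    exclusion audit; normative z-scoring against an HIV-negative reference with
    combination central-auditory scores and last-visit quantile grouping; linear
    mixed-effects trajectory models with group-by-time and group-by-age
    interaction tests; and a synthetic longitudinal cohort generator with
    learning effects, random subject trajectories, and dropout for end-to-end
    validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
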