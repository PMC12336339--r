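Package: srscore
Title: Stressor Reactivity Scores and Resilience Factors in Multi-Wave Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residual-based quantification of resilience in longitudinal
    questionnaire cohorts. Scores proportional stressor exposure (E) from a
    dichotomised stressor item bank, scores mental-health problems (P) with the
    PHQ-9 and GHQ-12, fits the sample's normative E-P regression line (linear or
    quadratic, selected by a likelihood-ratio chi-squared test) and takes each
    individual's residual as their stressor reactivity (SR) score. Provides the
    downstream inference chain: time-trend models on complete cases, cumulative
    baseline-exposure effects, resilience-factor associations (unadjusted and
    covariate-adjusted), a multivariate model, exposure-moderated regression with
    simple slopes, and Baron-Kenny mediation with a seeded case-resampling
    bootstrap of the indirect effect. Includes a calibrated synthetic multi-wave
    cohort generator with compound-symmetric ordinal item blocks, dropout, new
    entrants and configurable structural effects, and an end-to-end pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
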