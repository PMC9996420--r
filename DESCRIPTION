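Package: passivesense
Title: Behavioral Features from Passive Smartphone Sensing and
    Within/Between-Person Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts behavioral measures from timestamped smartphone
    interaction event streams (screen sessions, per-app foreground usage,
    keystroke dynamics): hourly app count, normalized Shannon app entropy,
    hourly median session duration, hourly median typing interval, and daily
    nighttime screen time. Aligns the measures with biweekly-recalled
    depressive symptom items over 14-day windows with data-sufficiency
    filtering, disaggregates predictors into within-person and between-person
    components, and fits two-level linear mixed models with independent
    (diagonal) random slopes by restricted maximum likelihood, with Wald
    inference for fixed effects and parametric-bootstrap confidence intervals
    for variance components. Includes seeded synthetic-data generators for
    window-level model data and raw event streams with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
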