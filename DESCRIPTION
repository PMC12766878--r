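Package: icmetrics
Title: Time-Dependent Predictive Accuracy Metrics for Interval-Censored
    Competing-Risks Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates time-dependent predictive accuracy metrics -- the area
    under the ROC curve, the Brier score, and the expected predictive
    cross-entropy -- over a clinical window of interest [t, t+dt) for
    risk-prediction models when the primary event is interval-censored
    between periodic examinations and subject to a competing risk.  Two
    estimation approaches are provided: a model-based approach that weights
    every subject at risk by its probability of being a case or a control
    derived from the prediction model's own cumulative incidence function,
    and an inverse-probability-of-censoring-weighting (IPCW) approach that
    uses only subjects whose case/control status is known.  The package also
    ships a joint longitudinal-survival data simulator emulating an active
    surveillance cohort (repeat biomarker measurements, biopsy-detected
    progression, early treatment as a competing risk, right censoring) and a
    study runner that compares the approaches against the no-censoring
    reference by root mean square error.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    splines,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
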