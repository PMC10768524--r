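Package: ildgapm
Title: ILD-GAP and ILD-GAPM Prognostic Scoring and Survival Evaluation for
    Interstitial Lung Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements the ILD-GAP and ILD-GAPM composite prognostic
    scoring systems for interstitial lung disease (point assignment from
    diagnosis subtype, sex, age, percent-predicted FVC and DLco, and blood
    monocyte ratio; stage assignment; six-zone semiquantitative HRCT global
    scores), together with the survival-analysis machinery used to evaluate
    such clinical risk scores: Kaplan-Meier estimation, k-group log-rank
    tests, Harrell's concordance index, IPCW time-dependent ROC AUC at a
    fixed horizon with bootstrap confidence intervals, and univariate Cox
    partial-likelihood fits with Efron tie handling and AIC. A synthetic
    cohort generator with a calibrated proportional-hazards event-time
    model makes the whole evaluation pipeline testable without patient
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
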