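Package: quadriplanes
Title: Multi-Plane CAD Decision Fusion and Reader-Study Evaluation for
    Breast Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating computer-aided diagnosis (CAD) of breast
    lesions on ultrasound when several imaging planes of the same lesion each
    receive a dichotomous "possibly benign"/"possibly malignant" call.
    Implements the cross-planes (any-of-2) and quadri-planes (k-of-4) fusion
    rules, the associated one-level BI-RADS category adjustment used in
    combined reader+CAD reading modes, and the full diagnostic-accuracy
    toolkit of a paired reader study: 2x2 metrics with exact ratios, the
    McNemar test (exact and continuity-corrected), Cohen's kappa with the
    standard agreement bands, empirical ROC curves over ordinal scores with
    tie-corrected AUC, the Hanley-McNeil standard error and correlated-AUC
    z-comparison, Youden-index cutoffs, and two-proportion comparisons.
    A calibrated synthetic-cohort generator produces lesion cohorts with
    correlated per-plane binary CAD calls (latent equicorrelated Gaussian
    thresholding) and ordinal-probit reader BI-RADS scores sharing a latent
    severity, so every pipeline stage is testable without patient data.
    Packaged fixtures carry the reference study's printed contingency tables
    for exact reproduction of its metric panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
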