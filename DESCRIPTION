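Package: dosetrend
Title: Dose-Response Meta-Analysis of Category-Level Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage dose-response meta-analysis for published category-level
    cohort results. Reconstructs the within-study covariance of correlated log
    relative risks from category margins (Greenland-Longnecker pseudo-counts),
    fits per-study linear and restricted-cubic-spline trends by generalized
    least squares, pools them by fixed- and DerSimonian-Laird random-effects
    models with Cochran Q / I-squared heterogeneity diagnostics and the Higgins
    test-based I-squared confidence interval, tests nonlinearity via a Wald
    test on the second spline coefficient, and provides Egger / Begg
    publication-bias tests and leave-one-out sensitivity analysis. Includes a
    synthetic-data generator for category-level cohort studies with a known
    true dose-risk relationship, used for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
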