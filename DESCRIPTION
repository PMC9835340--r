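Package: confbias
Title: Bias from Misspecified Confounder Functional Forms in Exposure-Effect
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify the bias introduced in confounder-adjusted
    exposure-effect estimates when a truly non-linear confounder-exposure or
    confounder-outcome association is misspecified as linear.  Implements four
    confounder-adjustment estimators (multivariable regression, covariate
    adjustment using the propensity score, stabilized inverse probability
    weighting, and double-robust estimation), flexible functional-form bases
    (quantile categorization, polynomial terms, linear and restricted cubic
    splines), regression-based linearity diagnostics, and a Monte Carlo
    simulation engine that runs a condition grid over specification scenarios,
    sample sizes and effect sizes, reporting absolute and relative bias.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
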