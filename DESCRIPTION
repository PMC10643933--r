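Package: betadose
Title: Robust Dose-Response Curve Estimation with Penalized Beta Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of median-effect dose-response curves for in vitro
    potency screens using beta regression in the mean-precision
    parameterization. Fits are obtained by ridge-penalized iteratively
    re-weighted least squares with cross-validated selection of the tuning
    parameter; an optional minimum density power divergence estimator gives
    outlier-robust fits. User-specified potency levels (ICx/ECx) are
    estimated with delta-method standard errors and confidence intervals on
    the log10-dose scale, and agents are compared by pairwise Wald tests of
    equal potency or equal Hill coefficient with optional Holm adjustment.
    Includes a synthetic-data generator for beta-distributed responses with
    controllable extreme-observation patterns, summary-table writers, and a
    batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
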