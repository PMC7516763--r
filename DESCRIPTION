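Package: picsel
Title: Robust Model Selection with Pseudodistance-Based Information Criteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Minimum pseudodistance (gamma-divergence) estimation for
    univariate normal and normal-error linear regression models, and the
    pseudodistance-based information criterion (PIC) built on it: a robust,
    asymptotically unbiased estimator of the expected overall discrepancy
    between the true model and a fitted candidate. Includes the comparator
    criteria AIC, BIC and MDIC (the latter based on the density power
    divergence), all-subsets candidate enumeration and selection,
    influence-function diagnostics with gross-error sensitivities, a
    contaminated-regression Monte Carlo harness for selection-proportion
    studies, and the Hald cement data as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
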