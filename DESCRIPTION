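Package: prevratio
Title: Prevalence Ratio Estimation for Cross-Sectional Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of prevalence ratios (PR) from cross-sectional
    binary-outcome data using a negative binomial generalized linear model
    with log link ("negative log-binomial") and sandwich (robust) variance,
    together with the standard comparison battery: crude and Mantel-Haenszel
    stratified 2x2 estimation with Greenland-Robins variance, log-binomial,
    log-Poisson (Cox constant-time) and logistic regression fitted by
    iteratively reweighted least squares with step-halving, BIC model
    selection, precision and confounding-percentage metrics, an exhaustive
    integer reconstruction of 2x2 tables from published summary statistics,
    and a seeded synthetic-cohort generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    sandwich
Config/testthat/edition: 3
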