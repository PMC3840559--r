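Package: lexpit
Title: Additive-Multiplicative Absolute Risk Regression for
    Population-Based Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linear-expit ('lexpit') regression, an
    additive-multiplicative model for the absolute risk of a binary
    outcome, to population-based case-control data. Absolute risk over a
    fixed risk period is modeled as the sum of a linear (risk-difference)
    term and an inverse-logit (residual odds ratio) term. Estimation
    maximizes a sampling-weighted pseudo-log-likelihood under feasibility
    constraints that keep every observed covariate pattern's fitted risk
    inside the probability scale. Expansion weights are built from a
    stratified sampling design (cases self-ascertained, controls weighted
    by inverse sampling fractions). Variance estimation uses
    influence-function linearization with a stratified bootstrap
    alternative. Includes goodness-of-fit and effect-scale diagnostics
    (weighted Hosmer-Lemeshow, risk-exposure scatter, dual-scale
    comparison) and a synthetic stratified case-control study generator
    with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
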