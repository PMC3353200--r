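Package: medtotal
Title: Total Effects in Mediated Longitudinal Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Estimation and Monte-Carlo evaluation of the total effect of a
    repeated binary predictor on a repeated binary outcome in the presence of
    a continuous mediator. Provides a latent-growth structural-equation data
    generator with probit or logit measurement error, maximum-likelihood
    fitting of binary-outcome mixed models with correlated random intercept
    and slope via adaptive Gauss-Hermite quadrature, scale-factor conversion
    between mediator-conditional and mediator-marginal coefficient scales,
    product-of-coefficients total effects with delta-method standard errors,
    and a seeded simulation harness summarising bias, coverage probability
    and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    statmod,
    withr,
    parallel
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mvtnorm,
    numDeriv,
    optparse,
    yaml
Config/testthat/edition: 3
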