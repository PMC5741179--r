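Package: semijm
Title: Joint Models for Longitudinal Outcomes and Semicompeting Risks of
    Dropout and Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Likelihood-based joint modelling of a Gaussian longitudinal
    outcome truncated by semicompeting risks of dropout and death. A linear
    mixed model with random intercept and slope is linked to discrete-time
    probit hazards for dropout and for death through shared random effects.
    The marginal likelihood is available in closed form via multivariate
    normal orthant probabilities, so maximum likelihood estimation with
    profile-likelihood intervals is supported; a conjugate Gibbs sampler
    with truncated-normal augmentation provides Bayesian estimation.
    Partly-conditional ("alive at visit j") mean profiles follow from the
    closed skew-normal distribution of the random effects given survival.
    Includes a simulator for HERS-like cohorts, posterior predictive model
    checking with a chi-square discrepancy, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    jsonlite,
    mvtnorm,
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nlme,
    numDeriv,
    rjags,
    mnormt,
    statmod,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
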