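Package: proxlvm
Title: Unified Stochastic Proximal Estimation of Latent Variable Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quasi-Newton stochastic proximal optimization for penalized and
    constrained marginal maximum likelihood estimation of latent variable
    models. Alternates a stochastic imputation step (exact sampling or
    Gibbs sampling with adaptive rejection sampling) with a diagonally
    scaled proximal gradient update, followed by Polyak-Ruppert averaging.
    Complete back-ends are provided for logistic item factor analysis
    (confirmatory, and exploratory with lasso or elastic-net regularized
    loadings) and for restricted latent class models for cognitive
    diagnosis with monotonicity constraints enforced by quadratic
    programming. Includes a Gauss-Hermite quadrature EM reference solver,
    Louis-formula observed-information estimation as an algorithm
    by-product, synthetic-data generators, and simulation-study drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
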