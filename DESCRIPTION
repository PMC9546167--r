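Package: flowvine
Title: Vine Copula Flows for Mixed Continuous and Discrete Dependencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric modeling of multivariate dependencies among mixed
    continuous and discrete variables with canonical vine (C-vine) pair-copula
    constructions whose margins and bivariate copulas are estimated by
    rational-quadratic spline normalizing flows on a uniform base. Provides
    closed-form Clayton, Frank and Gaussian copulas as simulation ground truth,
    the distributional transform for discrete margins, maximum-likelihood flow
    training with random hyperparameter search, inverse-Rosenblatt sampling,
    Monte-Carlo copula entropy, a k-nearest-neighbor Kullback-Leibler
    divergence estimator, a simulation benchmark against parametric vines, and
    utilities for binning spike-event tables and selecting correlated neuron
    modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
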