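Package: pebgroup
Title: Iterative Empirical Bayes for Group Inversion of Nonlinear
    Dynamic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical (parametric empirical Bayes) inversion of
    nonlinear dynamic models of multi-subject, multi-condition
    time-series data, in the style of dynamic causal modelling group
    studies. Provides Gaussian-density algebra with analytic Bayesian
    model reduction, a variational-Laplace (Gauss-Newton) first-level
    scheme, a second-level general linear model furnishing empirical
    priors, an iterative group-inversion loop with a log-determinant
    convergence rule that finesses local maxima, exhaustive
    second-level model search with Bayesian model averaging, and a
    synthetic multi-subject evoked-response study for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
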