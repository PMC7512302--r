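Package: spinsc
Title: Stochastic Complexity of Spin Models with Interactions of Arbitrary Order
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for maximum-entropy spin models on n binary (+1/-1)
    variables with interaction operators of arbitrary order.  Provides the
    GF(2) operator algebra (bit-mask operators, rank, loop-group bases),
    gauge transformations and the partition of model space into complexity
    classes, exact partition functions with a loop (high-temperature)
    expansion, Fisher information, exact sampling and maximum-likelihood
    fitting, closed-form and Monte Carlo evaluation of the stochastic
    complexity (the log Jeffreys-prior volume that enters the minimum
    description length penalty), and MDL-penalized model scoring and
    selection for binary datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
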