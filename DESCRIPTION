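Package: mlnmix
Title: Parsimonious Mixtures of Multivariate Leptokurtic-Normal Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Model-based clustering with finite mixtures of multivariate
    leptokurtic-normal distributions, whose components are parameterized
    directly by mean, covariance and excess kurtosis.  Provides the 28
    parsimonious models obtained by crossing the 14 eigendecomposed
    covariance structures with equal or varying excess kurtosis, maximum
    likelihood estimation via a monotone majorize-minimize algorithm or a
    damped fixed-point algorithm, BIC model selection, the adjusted Rand
    index, and exact simulators for leptokurtic-normal, multivariate-t and
    generalized-hyperbolic mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
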