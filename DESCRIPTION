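Package: hetnma
Title: Informative Heterogeneity Priors for Bayesian Network Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian random-effects network meta-analysis for binary
    outcomes with externally informed prior distributions on between-study
    heterogeneity variances.  Implements four prior schemes that keep the
    contrast covariance matrix positive semidefinite (second-order
    consistency): a common heterogeneity variance, proportional variances
    with comparison-type specific priors, arm-based variances with a
    spherically parameterized correlation matrix, and a scaled inverse
    Wishart prior.  Ships data-based log-normal predictive distributions
    for heterogeneity by outcome type, moment-matching solvers that convert
    contrast-level target priors into arm-level or scaled-Wishart
    hyperparameters, an adaptive Metropolis-within-Gibbs sampler, prior
    Monte-Carlo characterization, and a generator of synthetic evidence
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    coda,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
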