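Package: plumevol
Title: Reversible-Jump MCMC Models of Plumage Pattern Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian comparative analysis of discrete plumage pattern
    evolution (uniform, irregular, regular and bimodal patterning) on
    phylogenies. Implements pattern-state coding from per-sex motif scores,
    clade-level frequency tabulation, a k-state continuous-time Markov
    pruning likelihood, reversible-jump Markov chain Monte Carlo over
    transition-rate configurations in which each directed rate is either
    fixed to zero or assigned to a shared-value rate class, Bell-number
    model-space priors with Bayes-factor model comparison, marginal
    transition probabilities, model-averaged ancestral root states,
    harmonic-mean and Ljung-Box convergence diagnostics, and a synthetic
    data generator (Yule trees plus exact stochastic character simulation)
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
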