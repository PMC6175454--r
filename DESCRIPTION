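Package: robustgen
Title: Robustness Genetics for Multi-Environment Aquaculture Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-genetic analysis of robustness in multi-environment
    fish breeding programs. Provides pedigree utilities (inbreeding, the
    additive numerator relationship matrix and its sparse inverse), a
    configurable breeding-program simulator with between- and within-family
    selection across several grow-out environments, a Bayesian multi-trait
    animal model that measures genotype-by-environment interaction through
    cross-environment genetic correlations, and a genetically structured
    environmental variance model (double hierarchical animal model) that
    quantifies genetic heterogeneity of residual variance, i.e.
    micro-environmental sensitivity. Both models are fitted by
    Metropolis-within-Gibbs MCMC with convergence diagnostics and highest
    posterior density summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
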