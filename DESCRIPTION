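Package: mtbayes
Title: Bayesian Multi-Trait Analysis and Selection Indices for Half-Sib Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gibbs sampling for a multi-trait mixed model of half-sib family
    trials with unstructured genetic and residual trait covariance matrices
    and inverse-Wishart priors. Provides MCMC convergence diagnostics
    (Geweke statistic, effective sample size, highest-posterior-density
    intervals), derived genetic parameters (heritabilities, genetic and
    phenotypic correlations), genetic-diversity clustering of posterior-mean
    genotypic values (Mahalanobis distance, Ward minimum-variance
    agglomeration, Mojena stopping rule), Hazel selection indices under
    configurable economic-weight scenarios, and a seeded simulator of
    complete randomized-block phenotype tables for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
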