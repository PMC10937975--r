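Package: speciationRI
Title: Reproductive Isolation Indices and Mixed Models Across a Speciation Continuum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates habitat and sexual isolation between pairs of
    populations from trial-level behavioral data, calibrates genome-wide
    F_ST from nuclear sequence divergence, and models the accumulation of
    reproductive isolation along a speciation continuum. Provides a
    conjugate Gibbs sampler for a Bayesian linear mixed model of pairwise
    isolation with crossed species random effects, DIC model comparison
    and Gelman-Rubin convergence diagnostics, single-breakpoint piecewise
    regression with BIC selection, auxiliary association statistics, and
    a synthetic-data generator emulating the study design for parameter
    recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    coda,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    rjags,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
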