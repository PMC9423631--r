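Package: cognoise
Title: Sampling-Algorithm Models of the Structure of Cognitive Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the temporal structure of cognitive noise
    through the lens of sampling algorithms. Implements Random Walk
    Metropolis, Hamiltonian Monte Carlo and Metropolis-coupled MCMC
    (parallel tempering) samplers over Gaussian and Gaussian-mixture
    hypothesis spaces, task readout models that turn sampler traces into
    time-estimate series or inter-response-interval (IRI) series, 1/f
    spectral-exponent and heavy-tail exponent estimators with a power-law
    versus exponential tail comparison, synthetic-data generators with
    known ground truth (fractional Gaussian noise, Pareto variates, Levy
    flights, patchy semantic spaces), and likelihood-free model comparison
    by Approximate Bayesian Computation with group-level protected
    exceedance probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
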