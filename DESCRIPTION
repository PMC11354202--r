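Package: tvddm
Title: Bayesian Estimation and Comparison of Drift-Diffusion Models with
    Time-Varying Drift Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation, Bayesian parameter estimation and model
    comparison for two-choice evidence-accumulation models: the standard
    drift-diffusion model (DDM) with between-trial variability and a
    time-varying drift-rate variant (TV-DDM) in which perceptual
    integration modulates the drift through an incomplete-gamma growth
    function.  Likelihoods are approximated by kernel density estimation
    over simulated defective response-time distributions (probability
    density approximation), posteriors are sampled with two-stage
    differential-evolution MCMC with a purification step, and marginal
    likelihoods for Bayes factors are computed by thermodynamic
    integration.  Includes response-time distributional measures
    (CDF and conditional accuracy functions), a posterior overlap
    indicator for repeated-measures effects on parameter estimates,
    and a synthetic-data generator for factorial noise designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
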