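Package: dvtrace
Title: Single-Trial Decision-Variable Signals from Neural Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the drift-diffusion decision variable on single
    trials. Simulates a bounded anticorrelated race accumulator model with
    linearly collapsing bounds and fits it to choice and reaction-time data by
    maximum likelihood; generates synthetic neural populations (target-in,
    motion-in, and untuned neurons) whose Poisson spiking is driven by the
    latent decision variable; derives coding directions (ramp regression, PCA,
    Tin averages, What and When decoders) and renders single-trial population
    signals; checks those signals against closed-form variance and
    autocorrelation theory for boxcar-smoothed Wiener processes; and quantifies
    the leverage of single-trial signals on choice and reaction time, including
    mediation by later samples, bootstrap and permutation nulls, and analyses
    of direction-selective neuron latency and coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    glmnet,
    generics,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
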