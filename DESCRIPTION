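Package: ppgranger
Title: Granger Causality for Ensemble Neural Spike Trains via Point-Process Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed functional connectivity between simultaneously
    recorded neurons from their spike trains. Each neuron's conditional
    intensity is modelled as a log-linear function of windowed spiking
    histories of the whole ensemble (a point-process GLM); the causal
    influence of one neuron on another is measured by the point-process
    log-likelihood ratio between the full model and a re-optimised model
    that structurally excludes the trigger neuron's history. Deviance
    differences are tested against chi-squared references under
    Benjamini-Hochberg false-discovery-rate control, yielding signed
    excitatory/inhibitory/none connectivity maps. Includes a ground-truth
    network simulator (per-bin Bernoulli thinning with absolute refractory
    enforcement and optional log-intensity noise), AIC history-order
    selection, time-rescaling Kolmogorov-Smirnov goodness-of-fit, and a
    command-line interface for simulation, inference, and Monte-Carlo
    false-discovery-rate experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
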