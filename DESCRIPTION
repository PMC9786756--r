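Package: scrmove
Title: Movement-Integrated Spatial Capture-Recapture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and maximum-likelihood inference for spatial
    capture-recapture (SCR) models with explicit animal movement processes.
    Provides discrete-time movement kernels (simple, correlated, and biased
    random walks, behavioural state-switching, potential-function and
    approximate Langevin diffusion resource-selection models) and their
    limiting distributions; Poisson and binomial point-process models for
    abundance and initial locations, including a resident/transient mixture;
    Gaussian and integrated-hazard detection models; an end-to-end synthetic
    data generator; and a hidden-Markov-model likelihood that discretizes the
    state space into pixels, marginalizes latent trajectories with a scaled
    forward filter over sparse transition matrices, and estimates abundance
    via the semi-complete-data likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
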