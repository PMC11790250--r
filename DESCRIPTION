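Package: mintdecode
Title: Mesh of Idealized Neural Trajectories for Neural Population Decoding
Version: 0.1.0
Authors@R:
    person("MINT", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decode behavior from neural population spiking by maximum-likelihood
    search over a library of idealized neural trajectories, with local
    interpolation between trajectories. Provides library learning from
    trial-structured data (Gaussian filtering, Type I/II trial averaging,
    PCA-based smoothing across neurons and conditions, circular-variable
    averaging, session-section adaptation), a precomputed Poisson
    log-likelihood lookup table with a recursive per-bin update, Newton's-method
    interpolation on the concave spike log-likelihood, causal and acausal
    millisecond-resolution decoding, evaluation metrics (decoding R2 including
    circular variables, bits per spike, PSTH R2, SNR channel filtering, neuron
    dropping), and a synthetic spiking-data generator with ground-truth labels
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
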