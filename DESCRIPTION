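Package: gaintrack
Title: Tracking Synaptic Gain Modulation from Spectral Neural Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end synthetic pipeline for explaining predictability
    effects in rapid auditory tone sequences through slow modulation of
    synaptic gain. Implements a two-source canonical-microcircuit neural mass
    model, analytic cross-spectral density prediction from its linearization,
    variational-Laplace inversion with Bayesian model reduction and averaging
    over a five-model space, sliding-window Bayesian belief updating of
    gain-modulation parameters, induced time-frequency analysis, and
    elastic-net linking of parameter trajectories to sensor-level sustained
    field effects. Includes a tone-pip stimulus generator and a ground-truth
    scenario builder so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    signal,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
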