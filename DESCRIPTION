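Package: gdcm
Title: Generic Dynamic Causal Modelling of Coupled Neural Mass Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples heterogeneous neural mass models (a four-population motor
    cortex microcircuit and a five-population basal ganglia-thalamus model)
    into a single dynamical network, predicts complex cross-spectral densities
    from the linearized, delay-embedded system, and inverts multi-condition
    spectral data by Variational Laplace with condition-specific synaptic
    effects. Includes a synthetic-study generator (stochastic simulation,
    multivariate autoregressive spectral estimation, paired-condition designs
    with known ground truth) and group-level inference on condition effects
    with false discovery rate control. A registration interface allows new
    neural mass models to be added and coupled to the shipped ones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
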