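Package: cabletron
Title: Learning Nonlinear Dendritic Computation in Compartmental Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-compartment biophysical neuron simulator with coupled
    forward-sensitivity (variational) equations that quantify the influence of
    every synapse on the somatic voltage. Builds compartmental models from SWC
    morphology reconstructions or synthetic branched trees, integrates cable,
    Hodgkin-Huxley and AMPA/NMDA/GABA synapse dynamics with a tree-sparse
    implicit Euler solver, fits local plasticity kernels K(dt, v_dend) from
    spike-triggered averages of voltage gradients, and trains single neurons
    on nonlinear feature-binding tasks with a supervised voltage- and
    spike-timing-dependent learning rule. Includes parameterized rate/temporal
    Poisson input ensembles, noise and structured-connectivity manipulations,
    and analyses of the learned spatial and temporal processing strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
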