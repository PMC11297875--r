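Package: spikemode
Title: Operation Modes of Leaky Integrate-and-Fire Neurons in Trained Spiking Networks
Version: 0.1.0
Authors@R:
    person("spikemode", "developers", email = "spikemode@example.org", role = c("aut", "cre"))
Description: Simulates and trains feed-forward spiking neural networks of
    leaky integrate-and-fire (LIF) neurons on rate-encoded images, and
    quantifies each neuron's operation mode -- coincidence detector versus
    integrator -- from its spiking activity. For every output spike the
    membrane potential is backtracked to the contributing input spikes,
    yielding two measures: the number of effectively contributing input
    spikes and the effective integration interval. Includes a synthetic
    labeled-image generator with controllable brightness and intensity
    histogram shape, Poisson rate encoding, surrogate-gradient
    backpropagation-through-time training with Adam and stratified
    cross-validation, origin-constrained slope curves with offset-plus-power-law
    fits, and cumulative decay-ordered neuron ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
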