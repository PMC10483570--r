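Package: snnbench
Title: Benchmarking Single-Neuron Spiking Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-Euler simulation and systematic comparison of nine
    single-neuron spiking models (leaky integrate-and-fire and its
    non-linear variant, adaptive exponential integrate-and-fire,
    integrate-and-fire with spike-frequency adaptation, theta neuron,
    Hodgkin-Huxley, quadratic integrate-and-fire, Izhikevich, and the
    spike response model). Each model is available in two published
    parameter regimes (a millivolt-scale trace regime for spiking-activity
    figures and a dimensionless benchmark regime), with pulse-response
    trace recording, a seeded two-class Gaussian classification benchmark
    driven by per-sample constant currents, accuracy / error and pairwise
    performance-loss reporting, and itemised per-update arithmetic
    operation accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
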