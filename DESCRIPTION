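Package: eqspike
Title: Equation-Oriented Specification and Simulation of Spiking Neural Networks
Version: 0.1.0
Authors@R: person("eqspike", "developers", role = c("aut", "cre"),
    email = "eqspike@example.org")
Description: Textual, unit-checked mathematical model descriptions for spiking
    neural networks: neuron dynamics as (stochastic) differential equations with
    physical units, threshold/reset/refractoriness events, synapses with pre/post
    spike statements, event-driven plasticity, summed variables and
    expression-based connectivity. Integration schemes (Euler, midpoint
    Runge-Kutta, Euler-Maruyama) are themselves textual descriptions that are
    combined symbolically with the model equations into executable abstract code,
    which can also be rendered as loop-style source text or as LaTeX model
    documentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'expr.R'
    'units.R'
    'dims.R'
    'equations.R'
    'abstract_code.R'
    'schemes.R'
    'neurons.R'
    'synapses.R'
    'network.R'
    'docgen.R'
    'modelfile.R'
    'eqspike-package.R'
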