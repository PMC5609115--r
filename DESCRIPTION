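Package: nadyn
Title: Intracellular Sodium Dynamics in Multicompartment Neuron Models
Version: 0.1.0
Authors@R:
    person("Nadyn", "Developers", email = "nadyn@example.org", role = c("aut", "cre"))
Description: A conductance-based multicompartment neuron simulator that treats
    intracellular sodium as a dynamic state variable. Sodium enters through
    voltage-gated and synaptic conductances, diffuses longitudinally along the
    dendritic tree, and is extruded by an electrogenic sodium-potassium pump
    described by a two-reaction kinetic scheme. Rising sodium lowers the sodium
    Nernst potential (spike and EPSP amplitude adaptation), raises the pump
    outward current (prolonged after-hyperpolarization) and slows calcium
    extrusion through the sodium-calcium exchanger, shifting the stable-state
    calcium concentration (synaptic tagging). The package ships reduced
    archetype morphologies for mitral-, pyramidal- and Purkinje-like cells,
    an SWC reader/writer, the stimulation protocols needed to exercise these
    effects (pulse trains, deterministic synaptic trains, climbing-fiber
    volleys, stochastic distributed input) and analytics for sodium entry
    ratio, effective capacitance and stable-state calcium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
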