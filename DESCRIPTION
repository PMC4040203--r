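Package: saccadegen
Title: Physiological Saccadic Burst Generator with a Muscle-Fiber Oculomotor Plant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates conjugate horizontal monkey saccades from the neural
    circuit up. A parallel-distributed midbrain network of eight neuron
    populations (long-lead, excitatory and inhibitory burst neurons, the
    omnipause neuron, tonic neurons, interneurons, and the abducens and
    oculomotor motoneuron pools) is built from conductance-based
    Hodgkin-Huxley axons, passive compartmental dendrites,
    FitzHugh-Nagumo tonic units, and current-pulse synapses. Motoneuron
    firing is converted by a first-order time-optimal controller
    (pulse-slide-step agonist, pause-step antagonist) into active-state
    tensions that drive a linear homeomorphic muscle-fiber oculomotor
    plant, yielding eye-position trajectories, main-sequence metrics,
    and per-neuron firing choreography for 4 to 20 degree saccades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
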