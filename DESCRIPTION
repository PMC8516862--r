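Package: assrbeta
Title: Theta-Neuron Microcircuit Simulation of Gamma-Band Auditory
    Steady-State Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a small auditory-cortex microcircuit of theta
    neurons (20 excitatory pyramidal cells, 10 inhibitory basket cells,
    one pacemaker drive cell) entrained by periodic click-train stimuli,
    and quantifies gamma-band (40 Hz) and beta-band (20 Hz) power of a
    simulated MEG signal. Implements schizophrenia-associated microcircuit
    alterations (prolonged IPSC decay, reduced GABAergic weights, reduced
    interneuron excitability), input-strength sweeps, and a beat-skipping
    index that links the emergent 20 Hz subharmonic under 40 Hz drive to
    alternating-cycle firing of the pyramidal population.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
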