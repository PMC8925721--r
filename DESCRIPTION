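Package: gapasym
Title: Asymmetric Electrical Synapses in Compartmental Thalamic Reticular Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of electrical coupling between
    Hodgkin-Huxley model neurons of the thalamic reticular nucleus (TRN).
    Builds single- and three-compartment TRN cells, couples them through
    gap junctions with independent directional conductances, and integrates
    the full system with a fixed-step second-order Runge-Kutta solver
    implemented in C++. Provides the standard measurement protocols for
    electrotonic coupling: coupling coefficients and their asymmetry ratio
    from hyperpolarizing step injections, spike-latency modulation under
    burst-like AMPAergic input, and phase of tonic spike synchrony from
    Hanning-filtered cross-correlograms. A closed-form passive nodal-network
    solver serves as an independent verification oracle for all subthreshold
    results, and sweep runners regenerate coupling, masking, latency and
    synchrony parameter maps as tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
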