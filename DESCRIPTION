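Package: allowave
Title: Time-Dependent Quantum Simulation of Allosteric Signal Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the propagation of a localized perturbation on a
    network of coupled sites as a quantum wave, the tight-binding and
    vibronic (exciton-bath) Hamiltonians that drive it, and the classical
    master-equation comparison. Characterizes the first passage of the
    perturbation wave at a designated active site by its arrival time,
    amplitude and temporal broadening, computes long-time transfer
    efficiencies, fits quadratic scaling laws in chain length, and supports
    non-Markovian population-coupled couplings, random environmental
    coupling modulation, Lanczos reduction of large site networks, and a
    library of model systems (chains, multipath networks, trumpets, grouped
    state sets).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
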