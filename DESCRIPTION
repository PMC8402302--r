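Package: memsyn
Title: Stochastic Memristive Synapse Between FitzHugh-Nagumo Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a neuromorphic interface in which a presynaptic
    FitzHugh-Nagumo oscillator drives a postsynaptic one through a
    metal-oxide memristive device. The device current mixes ohmic and
    Poole-Frenkel conduction weighted by a filament-fraction state
    variable, with normally distributed cycle-to-cycle fluctuations of
    the ion-migration barrier, the conduction barrier and the ohmic
    resistivity. Provides waveform generation, current-voltage sweeps
    with resistive-switching analysis, one-way coupled simulation of the
    two neurons, spike-train locking classification (1:1, n:1,
    intermittent), regime-map sweeps over coupling strength and drive
    amplitude, and ggplot2 visualisations. All results are returned as
    tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
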