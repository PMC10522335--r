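Package: hyphadialog
Title: Stochastic Two-Cell Dialogue Model and Oscillation-Trace Analysis for Fungal Hyphae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a stochastic excitable-oscillator model of chemical
    cell-to-cell communication between two fungal hyphae that secrete and
    absorb a shared extracellular signaling component, using Euler-Maruyama
    integration of a ten-variable Langevin system with distance-dependent
    coupling. Provides scenario drivers for single-cell monologue,
    fixed-distance dialogue, distance sweeps, approach ramps and media
    depletion; peak-based oscillation analysis of uniformly sampled intensity
    traces (inter-peak interval statistics, relative-frequency histograms,
    Pearson and windowed correlation, phase-relation classification,
    transition slowing); a seedable synthetic fluorescence-trace generator
    emulating tip-localized reporter pulse trains; and Stokes-Einstein
    Brownian-diffusion bounds on the size of the exchanged signaling particle.
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
    deSolve,
    withr
Config/testthat/edition: 3
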