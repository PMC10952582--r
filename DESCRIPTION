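Package: gabakin
Title: Kinetic Modelling of GABA-A Receptor Modulation by Sulfated Neurosteroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic Markov (Q-matrix) modelling of GABA-A receptor gating and
    its negative allosteric modulation by pregnenolone sulfate analogues. Provides
    S4 classes for kinetic schemes, rate sets, concentration-jump protocols and
    simulated whole-cell current traces; stiff-safe state-occupancy propagation by
    per-epoch matrix exponentials; packaged published scheme topologies with their
    printed rate constants; a virtual recording rig (pre-application /
    co-application protocols, peak and 20-s steady-state readouts, percent
    desensitisation); descriptive curve analysis (biexponential decay with weighted
    time constant, Hill concentration-inhibition fits with pIC50, ordinary least
    squares); rate-constant estimation by full-timecourse waveform fitting; and a
    seeded synthetic-data generator for noisy currents, dose-response tables and
    desensitisation-phenotype variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'scheme-core.R'
    'paper-schemes.R'
    'virtual-rig.R'
    'curve-analysis.R'
    'waveform-fit.R'
    'synthetic-data.R'
    'io.R'
    'cli.R'
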