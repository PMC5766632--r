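Package: navgating
Title: Gating Analysis of Voltage-Gated Sodium Channels: Simulation,
    Curve Fitting, and Mutant-Cycle Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of voltage-clamp gating data from
    voltage-gated sodium channels. Provides a Markov gating-scheme
    simulator (per-segment matrix-exponential propagation of
    piecewise-constant voltage protocols), a phenomenological generator
    of replicate-level normalized peak-current series for construct
    libraries, Boltzmann fits of steady-state inactivation,
    multi-exponential fits of recovery from inactivation,
    conductance-voltage fits of activation, thermodynamic
    double-mutant-cycle coupling energies with analytic error
    propagation, and mutational-screen summaries (midpoint shift tables,
    background-sensitivity correlations, and advisory outlier flagging).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'noise.R'
    'fit-boltzmann.R'
    'fit-activation.R'
    'fit-recovery.R'
    'fit-order.R'
    'gating-scheme.R'
    'io.R'
    'pheno.R'
    'scenarios.R'
    'library.R'
    'mutant-cycle.R'
    'screen.R'
    'pipeline.R'
    'protocols.R'
    'propagate.R'
    'simulate.R'
    'trace.R'
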