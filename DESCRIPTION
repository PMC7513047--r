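Package: activeblend
Title: Two-Temperature Active-Passive Polymer Blend Simulation and
    Interfacial Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained bead-spring (Kremer-Grest) molecular dynamics of
    polymer melts in which half of the chains are coupled to a hot Langevin
    thermostat and half to a cold one ("scalar activity"), together with the
    analysis toolkit for the resulting non-equilibrium phase-separated steady
    states: slab-resolved density, mean-square-velocity and effective
    temperature profiles, pressure-tensor profiles, order parameter and
    temperature-asymmetry diagnostics, entropy-production and sub-box
    fourth-order cumulant critical-point estimators, power-law binodal fits,
    and capillary-wave analysis of interface fluctuations (block height
    fields, mode spectra, interfacial stiffness and width scaling). Includes
    seeded synthetic-data generators so every estimator is testable without
    running molecular dynamics, a plain-text trajectory container with
    extended-XYZ import/export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
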