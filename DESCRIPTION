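Package: invivokin
Title: In Vivo Michaelis-Menten Enzyme Kinetics from Steady-State Strain Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating in vivo Michaelis-Menten parameters
    (K1/2_cell, Vmax_cell, kcat_cell) of pathway enzymes from steady-state
    strain panels. Includes a kinetic model of a constant-influx /
    Michaelis-Menten-conversion / growth-dilution pathway for experimental
    design, conversion of omics measurements (umol/gDCW, fmol/ug protein) to
    absolute intracellular concentrations, production fluxes from pool
    dilution at exponential growth, nonlinear least-squares fitting with
    Monte-Carlo uncertainty quantification and identifiability diagnostics,
    and a seeded synthetic strain-panel generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
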