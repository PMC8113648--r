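Package: socesim
Title: Simulation of Calcium Microdomains in ER-Plasma Membrane Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic reaction-diffusion simulation of store-operated
    calcium entry (SOCE) microdomains in a three-dimensional ER-plasma
    membrane junction of a T cell. Cytosolic and luminal (ER) calcium fields
    are solved on a graded rectilinear finite-volume grid with analytic
    singularity subtraction for the boundary fluxes carried by ORAI1
    channels, IP3 receptors and bidirectional SERCA pumps, including the
    discrete ER-calcium-sensed ORAI1 open-fraction function. Provides
    closed-form Green's-function oracles for verification, named scenario
    presets, observable extraction (junction amplitude, pore-mouth peaks,
    sensed ER averages, ion bookkeeping), and CSV/VTK exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
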