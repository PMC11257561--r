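Package: smdmtools
Title: Single-Molecule Displacement Mapping and Charge-State Analysis of
    Intermediate Filament Assembly
Version: 0.1.0
Authors@R: person("Maintainer", "smdmtools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the assembly state of intermediate filament
    proteins (vimentin, GFAP, keratins) from single-molecule
    displacement/diffusivity mapping (SMdM) data and from sequence-based
    electrostatics.  Includes a synthetic generator for paired-frame
    single-molecule displacement tables over a two-population diffusivity
    field, maximum-likelihood fitting of the SMdM displacement model per
    spatial bin, conversion of diffusion coefficients to average oligomer
    size via inverse-cube-root molecular-weight scaling, protein net-charge
    and isoelectric-point curves from Henderson-Hasselbalch titration, and
    ionic-strength/Debye-length characterization of buffer recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
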