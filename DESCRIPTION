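Package: retbudget
Title: Constraint-Based Models of Outer-Retina Energy Supply
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the supply side of an outer-retina energy
    budget. Builds cell-specific stoichiometric metabolic models from gene
    expression confidences, couples retinal pigment epithelium (RPE) and
    photoreceptor (PR) models through a shared extracellular interface,
    derives blood-tissue exchange bounds from published physiological
    constants (oxygen profiles, Fick's-law diffusion limits, arteriovenous
    differences, plasma concentrations), computes maximal ATP yield by flux
    balance analysis under light/dark and foveal/perifoveal conditions, and
    quantifies age- and eccentricity-dependent shifts in nutrient exchange
    per rod from choriocapillaris and rod-density data. Includes synthetic
    generators for a toy metabolic network with closed-form ATP yields,
    expression matrices with planted quartile structure, and aging tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
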