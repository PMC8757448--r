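Package: sorbcell
Title: Protein Sorption and Cell Adhesion Kinetics on Biomaterial Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic modelling of protein adsorption/desorption on a
    biomaterial disk and of subsequent cell attachment. Solves a 1D
    diffusion equation over a quiescent fluid column with Langmuir
    attachment/detachment kinetics at the disk face, fits the kinetic
    constants by exhaustive grid search against fluid-phase depletion and
    release time series, solves a two-compartment free/attached cell model
    in closed form, and couples the two processes through a saturating
    transfer function from surface protein coverage to the cell adhesion
    coefficient. Includes synthetic-data generators so every fitting stage
    is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
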