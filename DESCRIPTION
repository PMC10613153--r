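Package: arterysim
Title: Coupled Multiphysics Simulation of Arterial Atherosclerosis and
    Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite element simulation of arterial wall disease driven by
    vasa vasorum dysfunction. Couples finite-strain mechanics with
    multiplicative volumetric growth, steady nutrient diffusion-reaction,
    an Allen-Cahn phase field for inflammation or intramural hematoma, and
    a phase-field damage model with history-variable irreversibility,
    solved monolithically with Newton-Raphson and backward Euler time
    stepping. Includes a stochastic tree-fractal generator for the vasa
    vasorum network, annular mesh generation with local refinement,
    follower pressure loads, VTK time-series output and radial path
    post-processing for the two reference scenarios (wall thickening
    without rupture; hematoma-driven dissection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
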