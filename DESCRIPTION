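Package: tissuecal
Title: Inverse Finite-Element Calibration of Soft-Tissue Indentation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse finite-element modelling of rigid-probe
    indentation of homogeneous (lumped) soft tissue. Provides an uncoupled
    Neo-Hookean constitutive law with near-incompressibility enforced through
    a bulk-like penalty parameter, a displacement-driven nonlinear solver on
    ten-node quadratic tetrahedra with frictionless penalty contact against a
    rigid flat probe, and a slope-ratio calibration algorithm that fits the
    single material coefficient to experimental force-displacement records in
    a handful of iterations. Includes a Brent bracketing baseline, mesh
    convergence and bulk-ratio sensitivity protocols, Gmsh MSH / legacy VTK
    mesh input and output, synthetic limb-phantom generation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
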