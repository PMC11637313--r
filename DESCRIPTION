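Package: fides
Title: Force Inference from Deformable-Cell-Model Simulation of Embryo Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers relative mechanical forces in early embryos from 3D
    triangulated cell surface meshes. Implements a forward deformable cell
    model (cortical surface tension, volume conservation, cell-cell adhesion
    and repulsion, rigid eggshell confinement) with local active-force models
    for the cytokinetic ring and cell protrusions; an inverse shape-fitting
    procedure (FIDES) that optimizes surface tensions, adhesive tensions,
    target volumes and active-model parameters by stochastic accept-if-improves
    search on an area-weighted raycast deformation error; reference tangent and
    curved foam force inference (Young-Dupre junction-angle and Young-Laplace
    curvature solves); seeded synthetic-embryo benchmark generators; and
    cortical laser-ablation recoil analysis (Kelvin-Voigt exponential fits,
    frame-averaging bias correction, weighted bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
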