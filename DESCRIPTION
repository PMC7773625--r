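Package: fibreatlas
Title: Atrial Fibre Fields on Surface Meshes: Coordinates, Atlases and
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building, registering, averaging, comparing and
    exercising atrial fibre fields on triangulated open-surface meshes. A
    landmark-fixed two-coordinate atrial coordinate system is computed from
    Laplace-Dirichlet solves; fibre fields are expressed as angles in the
    local coordinate basis, mapped between anatomies, and averaged with
    circular statistics to form an atlas with per-element uncertainty.
    Fibre fields are visualised with streamlines traced in coordinate
    space, and their electrophysiological consequences are quantified with
    anisotropic monodomain simulations on single-surface and bilayer
    meshes: paced activation-time maps and their comparison metrics, and
    spiral-wave arrhythmia runs post-processed into phase-singularity
    density maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
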