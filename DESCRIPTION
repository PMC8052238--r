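Package: histowall3d
Title: Multi-Tissue 3D Reconstruction of Aneurysm Walls from Serial Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs watertight, multi-tissue 3D surface models of
    intracranial aneurysm walls from stacks of segmented 2D histology label
    images, and demonstrates the mechanical consequence of wall heterogeneity
    with a small-strain linear-elastic finite-element solver. The pipeline
    covers virtual inflation of postmortem-deflated lumina, Moore-neighbor
    contour extraction, coherent-point-drift slice registration, across-slice
    contour matching, parabolic end-capping, shrink-wrap surface meshing with
    boolean overlap cleanup, and per-tissue elastic material assignment with a
    homogeneous-versus-heterogeneous wall stress comparison. A synthetic
    phantom generator with analytic ground truth makes every stage testable
    without real histology.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    FNN,
    clue,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
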