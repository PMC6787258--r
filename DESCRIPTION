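Package: curvsense
Title: Membrane Curvature Sensing and Induction Analysis for BAR-Domain
    Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how banana-shaped (F-BAR)
    proteins sense and induce lipid-membrane curvature in coarse-grained
    simulation snapshots. Provides the Euler-elastica (Jacobi elliptic
    function) parametrization of a laterally buckled bilayer, mapping of
    protein position and orientation onto the buckle arc, Boltzmann-inversion
    free-energy profiles along the local radius of curvature with a
    density-of-states correction, least-squares circle fitting of bent
    membranes and protein backbones, RMSD/RMSF ensemble metrics, an
    elastic-theory estimate of the protein surface density needed to
    stabilize a membrane tube, synthetic ground-truth generators for all of
    the above, and readers/writers for GRO, PDB and labelled-XYZ coordinate
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    bio3d,
    dplyr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
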