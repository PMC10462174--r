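Package: discbelt
Title: Construction and Trajectory Analysis of Double-Belt Lipid Nanodiscs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing discoidal lipid nanodiscs
    stabilised by double-belt scaffold proteins, with a focus on
    apoE3-NT/DMPC particles. Provides a belt-builder that linearises a
    helix bundle and wraps two tandem chains per ring around a packed
    DMPC bilayer disc (parallel or antiparallel ring sense), a synthetic
    nanodisc generator with known ground truth for validation, and a
    trajectory analysis suite: mass density profiles with peak-based
    thickness and diameter estimates, Shrake-Rupley solvent accessible
    surface area, Kabsch superposition and backbone RMSD, inter-chain
    residue contact extraction and polar/nonpolar/ionic classification,
    and C-H (deuterium) order parameters with core/rim partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
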