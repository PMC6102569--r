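Package: dockeval
Title: Evaluation of Molecular Docking Poses Against Crystallographic
    References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Judges rigid-receptor docking output against crystallographic
    reference complexes. Provides binding-site definition and Kabsch
    superposition on binding-site C-alpha atoms, symmetry-corrected
    heavy-atom RMSD through bond-graph automorphisms, good/acceptable/bad
    pose classification, best-solution scoring positions under the s2 and
    s3 criteria with recurrence tables and cross-docking matrices,
    distance-constrained (ECIDAL) pose selection, grid-based binding-site
    volume and depth metrics, ligand descriptors (molecular weight and
    rotatable-bond count), and a synthetic docking-output generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
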