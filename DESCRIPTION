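Package: dentalseg
Title: Per-Face Semantic Segmentation of Dental Surface Meshes via
    Multiple Geometric Feature Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for semantic segmentation of 3D dental surface meshes
    into gingiva and individual teeth. Reads and writes STL, PLY and OBJ
    triangle meshes, extracts per-face geometric features (vertices,
    centroids, unit normals), decimates meshes by quadric edge collapse,
    and trains an attention-based neural network that encodes K-nearest
    neighbour centroid and normal-vector geometry in dual receptive-field
    branches with efficient channel attention, optimised with the
    generalized Dice loss. Includes a synthetic dental-arch generator for
    fully reproducible experiments, overall-accuracy and mean-IoU
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
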