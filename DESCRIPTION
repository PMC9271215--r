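Package: vasculomap
Title: Whole-Brain Cerebrovascular Network Tracing, Flow Simulation and
    Cortical Flatmapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of labeled three-dimensional
    cerebrovascular image volumes: channel subtraction and adaptive
    binarization of fluorescently filled vasculature, 26-neighbor
    skeletonization with endpoint reconnection and spur pruning into
    traced vessel graphs, regional length/branch/radius density
    statistics, Hagen-Poiseuille network-flow conductance tensors on
    local control volumes, Laplace-equation isocortical flatmaps,
    candidate-based cell detection with 2D-to-3D density conversion,
    and Bonferroni-corrected multi-region correlation analysis.  A
    synthetic-data module generates ground-truth vascular graphs,
    two-channel image volumes, layered cortical phantoms and Poisson
    cell fields so that the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
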