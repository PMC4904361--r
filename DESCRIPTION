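Package: tomopoly
Title: Classification of Polyhedral Shapes from Incomplete Cryo-ET Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying convex polyhedral shapes from individual,
    incomplete polyhedral graphs such as those extracted from cryo-electron
    tomography reconstructions with a missing wedge.  Provides a reference
    library of the 123 Platonic, Archimedean, Catalan and Johnson solids, a
    parallel-plane truncation simulator with random orientations, a
    231-dimensional topological profile with right-censored blocks for
    incomplete features, an empirical-density Bayes classifier plus SVM and
    LDA classifiers with a vertex-deletion robustness harness, and voxel
    morphometry utilities (directional-profile fusion, volume and sphericity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
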