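Package: kbinet
Title: Persistent-Homology Indices for Group-Wise Metabolic Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds group-wise correlation-distance networks from regional
    mean-uptake tables (for example FDG-PET standardized uptake values
    averaged over atlas regions), computes the zeroth persistent homology of
    the graph filtration (Betti number plot, integrated persistent feature
    and its slope), a kernel-based integrated persistent feature index
    measured against a control-derived template, and standard graph-theory
    indices (characteristic path length, network diameter, modularity) on
    Bonferroni-filtered networks.  Includes group-wise permutation
    inference, resampling-based leave-one-out support-vector-machine
    classification of univariate network indices, and a synthetic cohort
    generator with block-modular inter-regional correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    igraph,
    e1071,
    pROC,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
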