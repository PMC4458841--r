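Package: ectopo
Title: Functional Connectivity Topography of Medial Temporal Lobe Subregions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Seed-based intrinsic functional connectivity analysis of the
    entorhinal cortex and subiculum at high spatial resolution: synthetic
    BOLD cohorts with a planted connectivity gradient, volume-level
    preprocessing (spike flagging, Gaussian smoothing, task-effect
    residualization, ROI conditioning), first-level seed-to-voxel Fisher-z
    connectivity maps, voxelwise group statistics with permutation
    cluster-extent inference, gradient quantification along ROI axes
    (longitudinal and per-slice transverse partitions, within-subject
    factorial ANOVA), and cross-subject coordinate-based classification of
    voxel connectivity preference (leave-one-subject-out linear SVM with a
    permutation null).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
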