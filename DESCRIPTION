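Package: siliqueseg
Title: Silique Identification and Counting from 3D Point Clouds of Rapeseed Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and counts rapeseed (Brassica napus) siliques from dense
    3D point clouds reconstructed from smartphone video. Provides video keyframe
    selection (Laplacian-variance blur rejection and feature-matching similarity),
    point-cloud input/output with passthrough background filtering and
    farthest-point downsampling, an EdgeConv (dynamic graph CNN) semantic
    segmenter separating stem from canopy siliques, sparse-to-dense label mapping
    by kd-tree radius search, and silique counting by Euclidean clustering with
    iterative RANSAC line fitting, together with per-plant counting metrics
    (precision, MAPE, R squared) and a ground-truthed synthetic plant and frame
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
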