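Package: leafscan
Title: Morphometric and Local-Curvature Phenotyping of 3D Plant Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies plant morphology from segmented 3D point clouds of
    single plants or leaves. Estimates per-point surface normals by local
    least-squares plane fitting, computes a bounded local-curvature statistic
    that quantifies leaf blistering, and summarises it through histogram
    centroids and smooth-area fractions. Also extracts dimensional and
    volumetric traits (plant height, major/minor diameter, vertical projected
    area, bounding-box, convex-hull, columnar and voxel volumes, and canopy
    compactness), provides a tilted-plate benchmark for angle-estimation
    accuracy, reads and writes PLY/XYZ point clouds with scalar and normal
    colour maps, and generates synthetic scans (tilted plates, blistered leaf
    laminae, known-volume solids, mock rosettes) with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RANN,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readr,
    withr,
    optparse
Config/testthat/edition: 3
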