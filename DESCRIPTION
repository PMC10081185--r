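Package: vasctree
Title: Morphometry and Scaling Analysis of Vascular Spatial Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying whole-organ arterial networks represented
    as spatial graphs (centreline skeletons with per-point radii). Provides
    readers and writers for the AmiraMesh SpatialGraph ASCII dialect and a
    native tabular dialect, Strahler and topological (generation) ordering,
    per-segment morphometrics (radius, length, tortuosity, volume, branching
    angles, inter-vessel distances), scaling-law statistics (branching ratio,
    Murray's law regression with robust FDR outlier removal, extra
    sum-of-squares F tests, cross-dataset radius-scaling comparison),
    centreline correction for collapsed vessels (multiscale smoothing,
    radius restoration from cross-section perimeters), segmentation and
    skeleton validation metrics (topological precision/recall, a weighted
    five-term skeleton super-metric), compartmental (zonal) summaries, and a
    synthetic vascular-tree and phantom generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
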