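Package: spinemorph
Title: Morphometry, Model-Based Clustering and Simulation of Dendritic
    Spine Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of three-dimensional
    dendritic spine morphology from triangle surface meshes. The
    pipeline repairs fragmented or detached spine reconstructions with
    voxel morphology and slice-wise neck growth, extracts a 54-feature
    shape descriptor built from geodesic-distance level sets and
    boundary ellipses, clusters spines with full-covariance Gaussian
    mixtures selected by BIC, and simulates new watertight spine meshes
    from a fitted mixture via ellipse-skeleton triangulation and Loop
    subdivision. A synthetic-data module generates parametric
    spine-like meshes, corrupted variants and mixture-sampled feature
    populations with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rpart,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
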