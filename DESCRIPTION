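Package: curvemap
Title: Heatmap Representations of Elongated Structures in 2D and 3D
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes curves (centerlines, boundaries, implants and other
    elongated structures) in images and volumes as spatial heatmaps for use
    as regression targets in learning systems. Curves are fitted as
    smoothing B-splines with chord-length parameterization, resampled at
    uniform arc length, and rasterized by localized point-to-segment
    distance evaluation with a selectable distance-dependent profile
    (Gaussian, Laplace, triangular, rectangular, raised cosine or a
    simulated catheter cross-section) and reduction rule (minimum distance
    or inverse distance weighting). Includes a numerical line-integral
    oracle for the underlying convolution model, an approximation-error
    analysis on a parametric bend-curve benchmark, baseline curve
    representations (Gaussian blur, Gaussian-weighted distance transform,
    Gaussian-weighted cross-entropy response), a random-walk curve signal
    simulator, and evaluation metrics (average symmetric surface distance,
    boundary F-measure with ODS/OIS aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    splines,
    jsonlite,
    png,
    tiff,
    RNifti,
    EBImage,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
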