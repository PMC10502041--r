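# curvemap

Heatmap representations of elongated structures in 2D images and 3D
volumes.

Detecting lines, boundaries, centerlines and implant axes with learning
systems needs an *operational target*: a field the network can regress.
`curvemap` encodes a curve `C` and its positional uncertainty as a
heatmap — formally the convolution of the curve's arc-length distribution
with a radially symmetric filter,

    H(x) = ∫_C w(x − y) dy,

and approximates this line integral, exactly for straight lines and with
a measurable error elsewhere, by evaluating a 1D distance-dependent
profile on localized point-to-segment distances:

    H(x) ≈ h*(f_x),

where `f_x` collects the distances from `x` to the nearby polyline
segments of a fitted B-spline and `h*` is a reduction rule (minimum
distance, or inverse-distance weighting with power 1 or 2) composed with
one of six profiles `h` (Gaussian, Laplace, triangular, rectangular,
raised cosine, simulated catheter cross-section), each with compact
support `±3σ`. The package is aimed at researchers building
curvilinear-structure regression targets (surgical tool and anatomical
line detection, boundary detection, skeletonization) and at anyone who
needs to quantify how far such a distance-based encoding strays from the
true convolution.

Beyond target generation it ships the numerical line-integral oracle,
the bend-curve approximation-error benchmark, three baseline curve
representations (Gaussian blur, Gaussian-weighted distance transform,
Gaussian-weighted cross-entropy response), a seeded random-walk signal
simulator, and the two standard evaluation protocols (ASSD after Otsu +
thinning; boundary F-measure with NMS and ODS/OIS aggregation).

## Worked example

```r
library(curvemap)

pts <- controlPoints(rbind(c(40, 200), c(90, 110), c(160, 90), c(220, 140)))
crv <- fitCurve(pts, mode = "smooth")
crv
#> BSplineCurve: degree 3, 4 control points, 2D, S = 1.172 (RSS = 1.17)

poly <- samplePolyline(crv, m = 200)
poly
#> Polyline: 200 points (199 segments), length 263.2 px
maxCurvature(crv)
#> [1] 0.0147

kern <- kernelSpec("gaussian", sigma = 3)
hm <- renderHeatmap(poly, kern, reduction = "min", shape = c(256, 256))
hm
#> Heatmap: 256 x 256 grid, values in [0, 1]
writeHeatmap(hm, "curve.tif")           # 32-bit float TIFF

# recover the curve from its own heatmap and score it
ctr <- extractCenterline(hm)            # Otsu + Zhang-Suen thinning
gt  <- which(rasterizeCurve(poly, c(256, 256)) == 1, arr.ind = TRUE)
assd(ctr, cbind(gt[, 2] - 1, gt[, 1] - 1))
#> [1] 0.148
```

The fit honors the smoothing budget `S = n − √(2n)` (here 1.17 for four
points; `mode = "close"` interpolates instead), the polyline is sampled
at uniform arc length, the rendered peak-mode map lies in `[0, 1]` with
its crest on the curve, and the centerline recovered from the heatmap
sits 0.15 px from the generating curve.

How wrong can the distance approximation be? On the 2000×2000 bend-curve
benchmark (`buildBendCurve(delta)`; curvature grows with `delta`):

```r
rec <- approximationError(fitCurve(buildBendCurve(0.89), mode = "close"),
                          sigma = 34, reduction = "min")
rec
#>   sigma reduction kappaMax    L epsilon epsilonHat
#> 1    34       min   0.4416 2684   423.8     0.1579
```

At maximum curvature 0.44 px⁻¹ and width σ = 34 px, the minimum-distance
encoding deviates from the numerically integrated convolution by 16% of
the accumulated signal (`epsilonHat = ε/L`, with the profile normalized
to unit 1D integral). `errorSweep()` tabulates this over grids of
`delta`, `sigma` and reduction rules.

A command-line wrapper around the same functions is installed as
`exec/curvemap` (subcommands `heatmap2d`, `heatmap3d`, `simulate`,
`error-sweep`, `baseline`, `eval-assd`, `eval-fmeasure`; run with
`--help`).

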