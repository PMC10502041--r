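---
title: "Heatmap representations of elongated structures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heatmap representations of elongated structures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvemap)
```

## The model

An elongated structure -- a centerline, an anatomical reference line, a
catheter, an implant axis -- is a curve $C \subset \mathbb{R}^n$
($n \in \{2,3\}$) with positional uncertainty. Its heatmap is the
convolution of the curve's arc-length distribution with a radially
symmetric filter $w$,

$$H(\mathbf{x}) = \int_C w(\mathbf{x} - \mathbf{y})\, d\mathbf{y},$$

a non-negative scalar field that peaks on the curve and decays with
distance. Evaluating this line integral numerically for every cell of an
image is expensive. For an infinite straight line the integral collapses
to a function of the point-to-line distance alone,
$H(\mathbf{x}) = h(f(\mathbf{x}))$, where $f$ is the Euclidean distance to
the curve and $h$ is the 1D profile induced by $w$. The package's central
approximation applies this identity to general curves: evaluate a 1D
distance-dependent profile $h$ on localized point-to-segment distances.
This is exact for straight lines and accrues a quantifiable error with
curvature, which the `errorSweep()` machinery measures.

## Curve model

Curves enter as ordered data points (`controlPoints()`, at least two,
consecutive points distinct -- duplicates are rejected rather than
deduplicated because the chord-length construction divides by chord
lengths). `fitCurve()` builds one B-spline per coordinate over
chord-length parameters $t_i$ (cumulative chord length, rescaled to
$[0,1]$), with the degree set by the point count: cubic for five or more
points, quadratic for three, linear for two.

Two fitting modes exist. `close` solves the interpolation system exactly
(residuals below $10^{-6}$ px). `smooth` adds a second-difference
roughness penalty on the control points and chooses the penalty weight by
bisection as the largest weight whose residual sum of squares stays
within the automatic budget $S = n - \sqrt{2n}$ ($n$ data points). This
realizes the standard smoothing-budget criterion with fixed knots; it
does not insert knots adaptively. Both modes reproduce collinear data
exactly (affine functions lie in the penalty's null space).

`samplePolyline()` resamples the spline at uniform arc length: the curve
is pre-sampled at $20m$ parameter values, cumulative chord length is
accumulated, and the arc-length map is inverted by linear interpolation.
The resulting spacing is uniform to well under 1%, and the polyline
length underestimates the true length with second-order convergence
(verified against the analytic quarter-circle length in the tests).
`maxCurvature()` uses analytic spline derivatives on a dense parameter
grid; the default 2000 grid points agree with a 10-fold denser grid to
within 1%. The default sample count is $m = 200$.

## Kernels

Six profile families are available through `kernelSpec()`: Gaussian,
Laplace, triangular, rectangular, raised cosine, and a simulated
hollow-catheter cross-section with outer radius $r_o = 3\sigma$ and inner
radius $r_i = s\,r_o$, $s \in [0,1)$ (default $s = 0.5$). All have
compact support $|f| \le 3\sigma$. `peak` mode scales the maximum to 1
(for gradient-based learning targets); `pdf` mode carries the density
constants of the corresponding full-support distributions --
deliberately *not* renormalized after truncation, so the Gaussian and
Laplace profiles integrate to $\mathrm{erf}(3/\sqrt{2})$ and $1-e^{-3}$
over their support while the naturally compact families integrate to 1
exactly. For the catheter profile the peak normalization divides by the
projection maximum $\sqrt{r_o^2 - r_i^2}$ (attained at $|f| = r_i$), so
the stated goal $\max h = 1$ holds for every $s$.

## Rasterization

`renderHeatmap()` encloses each polyline segment in an axis-aligned box
dilated by $w/2 = 3\sigma$ per axis, plus end-cap boxes of side $w$
centered on the curve endpoints (axis-aligned squares/cubes; the hull
otherwise does not extend past the endpoints). Integer cell ranges are
rounded outward for enumeration and then filtered to the exact box, so
grid rendering and the continuous `evaluateHeatmapField()` collect
identical estimate sets. Within each box the exact point-to-segment
distance is computed; overlapping boxes contribute multiple estimates per
cell, combined by a reduction rule:

* `min` -- winner-take-all, $h(\min_i f_i)$, kept as a running minimum
  ($O(1)$ memory per cell);
* `idw1` / `idw2` -- Shepard inverse-distance weighting
  $\sum_i \lambda_i h(f_i) / \sum_i \lambda_i$, $\lambda_i = f_i^{-p}$,
  accumulated as running weight sums. A zero distance takes the
  continuous limit $h(0)$.

Cells in no box are zero; runtime scales with covered cells, not grid
size. Self-intersecting curves are rendered as-is with the chosen
reduction. In 3D the boxes become axis-aligned cuboids with cubic end
caps -- the axis-aligned enclosure of the right-prism hull.

## The line-integral oracle

`convolveLineIntegral()` supplies the ground truth that the
rasterization approximates. A design decision worth spelling out: the
model postulates that the straight-line heatmap equals the 1D profile
$h(d)$, so the oracle's radial filter must be the function whose
straight-line integral *is* $h$ -- the inverse Abel transform of the
profile, not the profile itself (the two coincide only for the Gaussian).
Closed forms are used: a radial Gaussian for the Gaussian profile,
$K_0(r/\sigma)/(\pi\sigma)$ for Laplace, $\mathrm{acosh}(R/r)/(\pi R)$
for triangular, $1/(\pi\sqrt{R^2-r^2})$ for rectangular, and -- fittingly
-- the uniform annulus for the catheter profile, which is literally the
X-ray projection geometry the profile models. The cosine filter is
inverted numerically and tabulated. Quadrature is composite midpoint over
uniform arc-length nodes (default 4000; log-singular filters are clamped
to their cell average near $r = 0$), with an optional doubling check and
an `adaptive` method that integrates each segment with breakpoints at the
filter's discontinuity radii -- needed for the edge-singular rectangular
filter, where fixed-node midpoint converges too slowly.

## Approximation-error analysis

`buildBendCurve()` reproduces the three-point benchmark on a
$2000 \times 2000$ px grid; $\delta \in [0,1)$ steers the maximum
curvature at the central point (at $\delta = 1$ the two outer points
coincide and the configuration degenerates into a 180-degree hairpin, so
it is rejected; the default sweep stops at 0.9). The error statistic
accumulates, over 121 offset levels spanning $[-3\sigma, 3\sigma]$, the
absolute difference between the level-set integral of the oracle and of
the distance-based field, using 500 on-curve evaluation points with
chord-length trapezoid weights and offset points placed along analytic
normals; with the profile normalized to unit 1D integral (`pdf` mode)
the normalized error $\hat\varepsilon = \varepsilon / L$ is the fraction
of the accumulated signal. These discretization sizes keep the
quadrature error below 1% on test configurations. The curvature reported
for each configuration is computed on the close ($S=0$) fit: the sweep
studies geometry, not smoothing.

Two honest caveats, both verified in the tests:

* For a *finite* curve the oracle decays at the curve tips differently
  from the distance-based field, contributing an end-truncation error of
  order $\sigma/2L$ even for straight lines. `approximationError(...,
  trimEnds = TRUE)` restricts evaluation to arc positions at least
  $3\sigma$ from the tips, isolating the curvature-induced error; the
  straight-line exactness test uses it. The bend-curve sweep keeps the
  full-curve statistic.
* The printed sampling-rate bound returned by `nyquistRate()`,
  $r > 4\pi\kappa$, is implemented as stated although twice the
  associated maximum frequency $\kappa/(2\pi)$ is $\kappa/\pi$; the
  discrepancy is preserved rather than silently corrected.

On this benchmark the minimum reduction is the accurate choice: both IDW
schemes accumulate many large distance estimates from overlapping boxes
and sit at a substantially higher error floor (asserted as an invariant).
Errors grow with both curvature and width; once $6\sigma$ support
overlaps across the bend the representation degrades sharply.

## Baseline representations

Three related encodings are provided for comparison, all built on a
supercover raster (cells within 0.5 px of the polyline):
`mseBlurRepresentation()` (Gaussian low-pass of the curve cells,
peak-normalized), `edtGaussianRepresentation()` (exact Euclidean distance
transform evaluated through the Gaussian profile -- near-identical to the
min-reduction heatmap up to sub-cell discretization, with the caveat that
cells straddling the $3\sigma$ truncation edge flip by the step height
$e^{-4.5} \approx 0.011$ under any finite raster), and
`bceWeightedRepresentation()`. The binary-cross-entropy impulse response
is under-specified in the literature this mirrors; the implemented
interpretation weights each offset by the Gaussian pdf times the clamped
negative log of the peak-normalized Gaussian response
($\varepsilon$-clamped at $10^{-12}$), and is documented as this
package's interpretation, not asserted as canonical.

## Signal simulator

`sampleCurvePoints()` draws the point count from the integer uniform
$U[3,10)$, seeds the walk uniformly in $[10,246)^2$ of the 256 px
envelope, and steps with length $s \sim U[20,60)$ px and absolute heading
$\phi \sim U[-90^\circ, 90^\circ)$ -- the half-plane heading gives the
walks a directional flow resembling catheters and other stiff structures.
A walk leaving the region restarts the whole point set (bounded at 1000
retries); this acceptance-rejection truncates the *realized* step
distribution slightly, which is part of the model -- the distributional
tests therefore check the generator's laws with the region constraint
lifted. `composeImage()` applies the overlay
$X_{sim} = X_{img} + a\,H\,(1+Z)$, $Z \sim N(0, \sigma_Z^2)$ i.i.d.,
without clipping. The noise level $\sigma_Z$ has no canonical value;
the default is 0.1, exposed as a parameter. Backgrounds come from
`syntheticBackground()`, a seeded sum of low-frequency cosine waves
rescaled to $[0,1]$: it emulates only the smooth large-scale intensity
variation of a radiograph, not anatomy, texture or detector noise, so
pipeline tests passing on it say nothing about robustness to real
clutter -- real backgrounds can be substituted wherever a matrix is
accepted.

## Evaluation metrics

Signal recovery for evaluation follows two protocols.
`extractCenterline()` (Otsu threshold, then Zhang-Suen thinning in 2D or
sequential simple-point thinning with six directional subiterations in
3D) feeds `assd()`, the average symmetric surface distance. Thinning
branch artifacts are kept. `nmsHeatmap()` suppresses non-maxima along the
across-ridge direction (orientation from second derivatives of the
smoothed map; zero-gradient cells are kept, so constant maps pass
through), and `fMeasure()` matches prediction and ground-truth points
one-to-one within a tolerance $d_{max}$ (benchmark convention: 0.0075 of
the image diagonal) -- implemented as maximum-weight bipartite matching
with weight $C - d$, which is equivalent to a maximum-cardinality,
minimum-total-cost assignment, with a greedy fallback above 5000 points
per side. `odsOis()` sweeps 99 uniform thresholds and aggregates the
pooled-count optimum (ODS) and the mean per-image optimum (OIS).

## Problem sizes used in the test suite

The shipped tests exercise the full pipeline at desk scale: bend-curve
error records use 300--500 evaluation points, 121 levels and 1500--2000
oracle nodes; the representation-equivalence check runs at 10-fold
supersampling of a 256 px scene; the end-to-end recovery check renders
20 seeded simulator samples at $\sigma \in \{1,2,3\}$ and requires
sub-pixel ASSD. The acceptance script sweeps the printed bend grid with
the high-curvature end refined to $\delta$ steps of 0.01 (the coarse
printed grid contains no configuration with $\kappa_{max} \in
[0.25, 0.50]$ px$^{-1}$: curvature jumps from 0.13 at $\delta = 0.8$ to
0.54 at $\delta = 0.9$).

## Known limitations

* No per-point width modulation along the curve and no anisotropic
  kernels: structures of varying apparent width are out of scope.
* No periodic (closed-curve) splines and no adaptive knot placement
  beyond the smoothing budget.
* Self-overlap of wide heatmaps is rendered by the chosen reduction
  without special handling; at high curvature and large $\sigma$ this is
  exactly the regime where the approximation error peaks.
* The 3D thinning preserves topology via local simple-point tests; on
  noisy volumes it can leave short spurs, as any thinning does.
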