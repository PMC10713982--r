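---
title: "Rescaled morphodynamics: model, estimators, and study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescaled morphodynamics: model, estimators, and study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphodyn)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the estimators and their numerical choices, the
synthetic study conditions used throughout the tests, and the limits of what
those tests demonstrate.

## The model

### Deformation maps

The primitive object is the tissue deformation map `x = phi(X, t)`: the
position at stage `t` of the material point initially at `X`, on the frontal
plane, in micrometres. Axis 1 is proximo-distal (distal positive), axis 2
antero-posterior (anterior positive); a per-species `flip_ap` flag at import
brings differently oriented image data onto this one convention. The local
deformation is the gradient tensor `F = d phi / d X`: `det F` is the local
area growth ratio, and the principal stretches of `U = (F'F)^(1/2)` give the
anisotropy, summarized as `log(lambda1/lambda2)` (zero at isotropy,
symmetric under inversion of the ratio) with the major-stretch axis pushed
forward into the deformed configuration and reported modulo pi. The scalar
choice of anisotropy magnitude is ours; only the qualitative pattern of
"magnitude and orientation" is prescribed by the problem.

### Average growth and the rescaled (xi) space

A map is decomposed as

    phi(X, t) = L(t) xi(xi0, t) + xbar(t),      xi0 = X / C0,

where `C0` is the initial centroid size (root-mean-square distance of
equally arc-length-spaced boundary samples from their centroid; M = 200
samples, and the same `C0` normalizes the seeds, so the convention is
self-consistent), `L(t) = C0 * Fbar(t)` with `Fbar` the area-weighted
spatial average of `F` over the initial domain, and `xbar(t)` the geometric
centre of the deformed tissue. Two conventions close the system: the initial
area centroid is taken as the coordinate origin, and the material point
initially at the origin is pinned (`x(0, t) = 0` by subtracting its tracked
position). The rescaled position `xi = L^-1 (x - xbar)` is the cell's
position relative to the whole tissue after cancelling average growth; under
spatially uniform growth it is constant in time ("no flow"), so flow in
xi-space isolates the heterogeneous part of morphogenesis.

For `xbar(t)` we use the area centroid of the advected outline polygon
rather than a det-F-weighted quadrature mean. The two agree for exact maps,
but the polygon centroid is far more robust for maps fitted from noisy data,
whose Jacobians near the tissue boundary are extrapolations: weighting by a
noisy `det F` couples weight errors to position errors and can shift the
centre by tens of micrometres, which then contaminates every rescaled
trajectory.

### The xi velocity field

Differentiating the decomposition and using the star-domain representation
`x(X, t) = (int_0^1 F(eps X, t) d eps) X` (valid when the initial domain is
star-shaped about the origin and the map is smooth) gives

    d xi / d t = L^-1 (S_X - S) L xi - v_g,

with `S` the tissue-average velocity-gradient tensor defined through
`d Fbar/dt = S Fbar`, `S_X` its line-segment-average counterpart at the
focal cell, and `v_g = L^-1 (d xbar/dt - S_X xbar)` the centroid term, which
an `include_vg` switch can drop (the small-centroid-motion approximation).
`S` and `S_X` are computed from their defining relations by central
differences on the decomposition stage grid (one-sided at the ends, with a
warning), not by fitting a rate model. In one dimension the equation reduces
to the scalar form `d xi/dt = (S_X - S) xi - v_g`, which the test suite
verifies against closed-form tensors on an embedded 1D growth profile.

### Clock synchronization

Each species' staging scale is a chart on an abstract common clock. The
distance between two species at a stage pair is the mean Euclidean distance
between their rescaled positions over a shared seed set Omega (the regular
xi0-lattice inside the intersection of both initial outlines in xi-space,
fixed at the initial stages). Per-row and per-column argmins of the
stage-pair distance matrix define the composite stage maps in both
directions, with ties broken toward the earlier stage and an optional
parabolic sub-grid refinement of the minimizing stage used by the linear
correspondence fit. The synchronization is a homeomorphism only while both
composite maps are strictly monotone, jump by at most `tol` grid steps, and
invert each other within `tol` steps; `validity_range()` returns the largest
initial segment where all three hold. `overlap_region(shrink = )` can
restrict the seeds to the internal tissue: trajectories near the tissue
boundary are the ones that shape each species' own contour and are also the
least constrained part of a fitted map, so interior seeds carry the
cross-species signal with less nuisance. The worked analyses here use
`shrink = 0.8`.

### Region comparison and overfitting

A candidate sub-region of one species' bud is cut by three parameters: the
distal fraction `alpha` of the extent measured along a P-D axis through the
centroid, offset by `beta` (xi units) in the A-P direction and rotated by
`theta`. The extent is the chord of the axis line inside the outline, so
`beta` and `theta` genuinely change which tissue is retained; the cut itself
is a half-plane clip. The geometry of how three scalars cut a bud is not
uniquely determined by the problem statement; this construction is isolated
behind `region_from_params()` so alternatives can be swapped in. The
restricted system is fully re-decomposed on the clipped region (`C0`,
`Fbar`, `L`, `xbar` all recomputed) — the comparison must be between
self-contained rescaled systems — and its comparison frame is rotated by
`-theta` so the region's axis aligns with the partner's P-D axis. The fit
statistic `eta` is the temporal mean, over the source stages in the analysis
period, of the minimal distance to the partner's stage grid (and `eta_tilde`
its source/target-swapped mirror). Overfitting is measured by the population
coefficient of variation of `theta*(beta) = argmin_theta eta` across the
beta grid: when a region is over-restricted, the optimal orientation stops
being pinned by shared dynamics and wanders with the nuisance offset.

## Estimators

### Per-interval map regression

Each interval's pairs `(X_i, x_i)` are fitted as a polynomial trend (degree
1, i.e. affine, by default) plus a per-component Gaussian-process residual
with a shared squared-exponential kernel; length scale, signal and noise
variances maximize the log marginal likelihood (L-BFGS-B on log parameters,
bounded to sane ranges relative to the data diameter and residual variance).
The affine mean guarantees exact reproduction of noise-free affine data; the
GP part has an analytic Jacobian, so `F` needs no finite differencing for
fitted maps. Higher-degree trends (settable via `prior$degree`) fit single
intervals slightly better but extrapolate aggressively outside the data
hull, and since composition evaluates each interval at the previous
interval's output, polynomial extrapolation compounds across nine chained
fits; the affine default composes far more stably, which is why it is the
default. Orientation reversal of the fitted field is reported as a fold
warning, never silently accepted: fitted maps may genuinely fold locally
under noise.

### Composition, inversion, bootstrap

Within an interval, stages are reached by linear interpolation of the
displacement (consistent with the linear-in-stage interpolation of the spot
records themselves); across intervals the maps chain exactly, so the
configuration at an interval's end is identically the next interval's
input. Inversion is Newton iteration seeded from the nearest node of a
coarse evaluation grid, to `1e-6` micrometres. The bootstrap resamples each
interval's pairs with replacement at the original size (B = 150 by default)
and refits; by default replicates reuse the reference fit's hyperparameters
(`reoptimize = FALSE`) — per-replicate marginal-likelihood optimization
proved to destabilize the replicate ensemble more than it widened it.
Because resampling cannot see the smoothing component of the estimator's
uncertainty, `map_pointwise_sd()` propagates each interval's GP posterior
predictive variance through the composition chain (transported by the
downstream Jacobians); the pointwise spread of a reconstruction is the
root-sum-square of the bootstrap standard deviation and this posterior
width, and a bracketing band of three such spreads is used when checking
coverage of a known ground truth. With B = 30 replicates a raw min/max
envelope has only about 87% nominal two-coordinate coverage even for an
ideal unbiased estimator, which is why the band is SD-based rather than an
envelope.

## Numerical choices

- Area averages (`Fbar`, quadrature centroids) use cell centres of a
  bounding-box grid (default 25 per axis) with fractional weights for
  boundary-straddling cells (2 x 2 subsampling), making the averages
  second-order accurate; O(h) boundary error would otherwise dominate
  cross-species comparisons of `L`.
- Line-segment averages for `S_X` use Gauss-Legendre quadrature with 32
  nodes by default: near the domain boundary the integrand is only
  piecewise smooth and cheap quadrature visibly distorts the velocity
  field. `star_domain_identity_check()` offers a midpoint rule for
  convergence-order studies (second order), while Gauss is used for
  accuracy.
- Time derivatives on the stage grid are central differences, one-sided at
  the ends with a classed warning.
- Ground-truth synthetic maps integrate the flow with fixed-step RK4
  (default 200 steps over the common-time span) together with the
  variational equation `dJ/dtau = (dv/dxi) J`, so ground-truth deformation
  gradients are exact to integrator tolerance — necessary for the
  micrometre-level identity checks.
- Degenerate inputs error with classed conditions (collinear landmark
  configurations, zero-area outlines, empty region clips, empty overlaps,
  singular growth tensors); empty stage intervals warn and are reported in
  an attribute, never silently dropped.

## The synthetic study conditions

The generator plants a species-shared archetype flow `v(xi, tau)` as a
closed-form field: an anterior-directed drift (strongest posteriorly), a
proximo-distally increasing growth heterogeneity, and a tangential
boundary-layer swirl, each multiplied by the bump factor
`w = (1 - (xi1/a)^2 - (xi2/b)^2)^2` clamped at zero, which vanishes with its
gradient on a bounding ellipse. The squared form matters: it keeps the field
C1, so the smoothness assumption behind the line-integral machinery holds,
and trajectories started inside remain inside. The default strengths
(0.7, 0.4, 0.25 per common-time unit) were chosen once so that the flow's
nonaffine displacement per stage interval stands clearly above the
measurement noise of the default design while keeping `det F` comfortably
positive everywhere — the regime in which a per-interval smoother can
faithfully recover the dynamics, mirroring a study system where the flow is
"pronounced" rather than marginal.

Species are built from the flow by a growth schedule
`L(tau) = C0 R(omega tau) diag(exp(g1 tau), exp(g2 tau))` (defaults
`g = (0.8, 0.5)`: stronger P-D than A-P growth), an optional centroid drift,
a linear stage warp `t = a tau + b`, and an elliptical initial outline of
unit centroid size scaled by `C0`. The default two-species scenario uses
`C0` = 400 and 800 micrometres — the smaller bud about half the larger per
axis — with frog-like stages 50.6-54.4 over nine intervals and chick-like
stages 21-30.5. The measurement design emulates integrating 11 individuals:
nine observed over a single interval each and two spanning two intervals, so
the per-interval pair counts equal the configured targets exactly (default
`(113, 185, 67, 79, 226, 333, 256, 129, 270)`); spots are quasi-gridded
(lattice plus jitter) inside the advected outline and perturbed by iid
Gaussian noise of 10 micrometres per coordinate per measurement, which puts
single-interval mean fit residuals in the 15-20 micrometre range.

Planted-truth scenarios used by the tests:

- **Warp recovery:** two species from one flow with `t_B = a t_A + b`,
  species B reconstructed from noisy spots (150 pairs per interval), slopes
  0.5-3 recovered within 5% and intercepts within one grid step.
- **Divergence detection:** species B's flow acquires a posterior-directed
  drift after a known common time; the validity range ends within two grid
  steps of the onset.
- **Region conservation:** species C is a scaled, rotated copy of species X
  restricted to the distal fraction `alpha_true` (cut at a planted axis
  angle), while X carries a proximal swirl perturbation outside that
  region — the prospective-stylopod territory whose dynamics are species
  specific. Because a similarity transformation commutes with the
  decomposition, the restricted-X system at the true parameters equals C's
  exactly, so `eta` has a planted minimum; with measurement noise the
  optimal angle destabilizes below the true extent and the CV of `theta*`
  rises monotonically as `alpha` shrinks.

What these conditions do *not* emulate — and hence what passing tests do not
show about real data: outlines are smooth ellipses rather than measured bud
contours; the flow is stationary in tau and shared exactly rather than
approximately; staging error is absent (stage values are exact inputs);
noise is isotropic, homoscedastic and uncorrelated across measurements; and
the third (dorso-ventral) dimension is ignored throughout. In particular the
exact-conjugacy construction makes the region analysis cleaner than any real
species pair, where the conserved region's shape itself differs between
species.

## Known limitations

- The per-interval smoother is a reimplementation in the
  universal-kriging style (affine mean, stationary isotropic kernel), not a
  port of any particular published estimator; printed residuals from
  measured datasets are not expected to be reproduced exactly.
- Composite fitted maps accumulate smoothing bias across intervals; the
  recovered xi-flow amplitude is typically a few percent low at late
  stages, which is the dominant error in stage-warp slopes. Bootstrap
  resampling alone understates this; the posterior-width term in
  `map_pointwise_sd()` accounts for most of it.
- Stage-pair argmins are grid-quantized; the parabolic refinement reduces
  but does not remove discretization of the composite stage maps.
- The chord-based region geometry is one concrete realization of a
  three-parameter region family; conclusions about the conserved extent
  should be checked for robustness to that choice.
- Everything is two-dimensional (frontal plane). Late-stage morphogenesis
  with pronounced three-dimensional rearrangement is out of scope.
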