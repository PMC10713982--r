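# morphodyn

Comparative morphodynamics of developing tissues in rescaled spacetime.

## What this package is for

During organ development, homologous tissues of different species — the
textbook case being the hindlimb buds of chick and *Xenopus* — differ in
absolute size, aspect ratio, and developmental rate, yet appear to share the
same underlying pattern of internal tissue motion. `morphodyn` implements a
complete analysis pipeline for making that statement quantitative from
landmark data:

1. **Deformation-map reconstruction.** Sparse labeled-spot correspondences
   (positions of fluorescently marked cell clusters measured at successive
   stages in several individuals) are assembled into per-interval datasets
   and fitted as smooth maps x = φ(X, t): an affine trend plus a
   Gaussian-process displacement field, chained across intervals into a
   continuous, differentiable spatiotemporal map with deformation gradient
   F = ∂φ/∂X. Local area growth is det F; anisotropy is the log principal
   stretch ratio of U = (FᵀF)^{1/2}.
2. **Decomposition into average growth and rescaled dynamics.** The map is
   factored as φ(X, t) = L(t) ξ(ξ₀, t) + x̄(t), where L(t) = C₀·F̄(t) is the
   "multi-dimensional tissue size" (initial centroid size times the spatial
   average of F), x̄(t) the tissue centre, and ξ(ξ₀, t) the *rescaled*
   trajectory of the cell starting at ξ₀ = X/C₀. Under spatially uniform
   growth the ξ-velocity ∂ξ/∂t = L⁻¹(S̄_X − S̄)Lξ − v_g vanishes identically,
   so any residual flow in ξ-space is the size-free signature of
   heterogeneous morphogenesis.
3. **Developmental-clock synchronization.** Two species' stage scales are
   treated as charts on one common clock. The mean distance
   δ(t_A, t_B) = ⟨|ξ_A(ξ₀ᵢ, t_A) − ξ_B(ξ₀ᵢ, t_B)|⟩ over a shared seed set
   yields a stage-pair distance matrix whose argmin ridges define composite
   stage maps ψ_B∘ψ_A⁻¹ in both directions, their homeomorphism validity
   range, and a linear stage correspondence.
4. **Region-restricted conservation analysis.** A candidate sub-region of
   one species' bud (distal fraction α along an axis offset by β and rotated
   by θ) is re-decomposed as a self-contained system and compared against
   the partner species through the temporal-average distance η; the
   coefficient of variation of the optimal angle θ* across β quantifies
   overfitting, and the two curves together locate the anatomically
   conserved extent.
5. **Uncertainty.** Bootstrap resampling of landmark pairs (B = 150 by
   default) plus the propagated Gaussian-process posterior width give
   pointwise spread bands for every reconstructed position.

Because no public landmark dataset accompanies the measurements this kind of
study uses, the package ships a first-class synthetic generator: a shared,
closed-form archetype flow in τ-ξ spacetime, species-specific growth
schedules L(τ), linear stage warps, and a measurement design that emulates
integrating 11 individuals over 9 stage intervals with configurable spot
counts and micrometre-scale position noise. Every pipeline stage is tested
against this generator's ground truth.

## A worked example

Two synthetic species share one archetype flow; the larger ("chick",
C₀ = 800 µm, stages 21–30.5) is reconstructed from noisy spots and
synchronized against the smaller ("frog", C₀ = 400 µm, stages 50.6–54.4).
The planted stage warp is t_chick = 2.5·t_frog − 105.5.

```r
library(morphodyn)

flow  <- archetype_flow()
frog  <- make_species(flow, species_spec("frog",  C0 = 400, warp = c(3.8, 50.6)))
chick <- make_species(flow, species_spec("chick", C0 = 800, warp = c(9.5, 21)))

grid   <- stage_grid("chick", seq(21, 30.5, length.out = 10))
spots  <- sample_spots(chick, measurement_design(noise_sigma = 10, seed = 1), grid)
ivals  <- build_interval_datasets(spots, grid)
fits   <- lapply(1:9, function(k) fit_interval_map(ivals[ivals$interval == k, ]))
glance(fits[[1]])
#>   interval stage_start stage_end     n mean_residual lengthscale signal_var ...
#> 1        1          21      22.1   113          18.1        259.       184.
```

The first interval holds 113 landmark pairs (the generator reproduces the
integrated 11-individual design) and fits with a mean residual of 18.1 µm —
the scale set by the 10 µm per-coordinate measurement noise.

```r
fm        <- compose_maps(fits, outline = initial_outline(chick))
dec_frog  <- decompose(frog, stages = seq(50.6, 54.4, length.out = 15),
                       seed_spacing = 0.06, species = "frog")
dec_chick <- decompose(fm,   stages = seq(21, 30.5, length.out = 15),
                       seed_spacing = 0.06, species = "chick")

om   <- overlap_region(dec_frog$xi, dec_chick$xi, shrink = 0.8)  # internal tissue
dm   <- distance_matrix(dec_frog$xi, dec_chick$xi, omega = om)
dm
#> <stage_distance> frog (15 stages) x chick (15 stages), 545 shared seeds
maps <- composite_stage_maps(dm)
glance(fit_linear_correspondence(maps$ab))
#>   slope intercept max_residual     n
#> 1  2.47     -104.        0.166    15
```

The recovered stage correspondence (slope 2.47, intercept −104) matches the
planted warp (2.5, −105.5) to within a grid step — the two species' clocks
are synchronized purely from their rescaled tissue dynamics. The physical
maps then align through the time-variant linear operator
L_CX(τ) = L_chick(τ)·L_frog⁻¹(τ):

```r
tidy(interspecies_scaling(dec_chick$growth, dec_frog$growth, 27.5, 53.6))
#>   component       value
#> 1 stretch_major  1.89
#> 2 stretch_minor  1.84
#> 3 rotation_rad  -0.0171
```

i.e. at this pair of synchronized stages the chick tissue is a nearly pure
(≈1.9×) scaling of the frog tissue, with negligible rotation — the
interspecies scaling is recovered from data.

`autoplot()` methods exist for ξ-trajectory sets, stage-distance heatmaps
(with both composite stage maps overlaid), and region scans;
`plot_deformation_field()` draws the area-growth / anisotropy pattern of a
fitted map.

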