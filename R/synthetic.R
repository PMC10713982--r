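# Ground-truth two-species scenarios: a shared archetype flow v(xi, tau) in
# rescaled spacetime, species-specific average-growth schedules L(tau),
# centroid paths and linear stage warps, and a measurement design producing
# noisy labeled-spot tables. Every field is closed form with an analytic
# spatial Jacobian, so ground-truth deformation gradients are exact to
# integrator tolerance.

#' Reference outline for the archetype flow
#'
#' An elliptical limb-bud-like outline in dimensionless xi0 units, scaled to
#' unit centroid size, with the P-D semi-axis along axis 1.
#'
#' @param semi_axes Ellipse semi-axes (P-D, A-P) before normalization.
#' @param n Number of vertices.
#' @return Vertex ring (n x 2 matrix), centroid at the origin.
#' @export
reference_outline_xi <- function(semi_axes = c(1.05, 0.75), n = 96L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ring <- cbind(semi_axes[1L] * cos(th), semi_axes[2L] * sin(th))
  ring / centroid_size(ring)
}

#' Archetype flow in rescaled spacetime
#'
#' A smooth, closed-form velocity field v(xi, tau) on the reference outline,
#' with three strength parameters reflecting the qualitative features of limb
#' bud morphogenesis: posterior-to-anterior drift (`ap_asymmetry`), deviation
#' from spatially uniform proximo-distal growth (`pd_nonuniformity`), and a
#' tangential boundary-layer component (`boundary_swirl`). Every component is
#' multiplied by the bump factor w = (1 - (xi1/a)^2 - (xi2/b)^2)^2 (clamped at
#' zero), which vanishes with its gradient on the bounding ellipse, so the
#' field is C1 and trajectories started inside remain inside. All
#' strengths zero gives v = 0 identically.
#'
#' @param ap_asymmetry Anterior-directed drift strength (dimensionless per
#'   common-time unit).
#' @param pd_nonuniformity P-D growth-heterogeneity strength.
#' @param boundary_swirl Tangential boundary-layer strength.
#' @param semi_axes Ellipse semi-axes of the bump factor.
#' @return Object of class `archetype_flow`: list with `v(xi, tau)` (n x 2),
#'   `dv(xi, tau)` (n x 4 columns dv1/dx1, dv2/dx1, dv1/dx2, dv2/dx2), and
#'   the parameters.
#' @export
archetype_flow <- function(ap_asymmetry = 0.7, pd_nonuniformity = 0.4,
                           boundary_swirl = 0.25, semi_axes = c(1.05, 0.75)) {
  if (any(c(ap_asymmetry, pd_nonuniformity, boundary_swirl) < 0)) {
    abort("flow strengths must be >= 0", class = "morphodyn_value_error")
  }
  a <- semi_axes[1L]; b <- semi_axes[2L]
  cap <- ap_asymmetry; cpd <- pd_nonuniformity; csw <- boundary_swirl
  v <- function(xi, tau) {
    x1 <- xi[, 1L]; x2 <- xi[, 2L]
    w <- pmax(0, 1 - (x1 / a)^2 - (x2 / b)^2)^2
    s <- csw * w * (1 - w)
    cbind(cpd * w * (x1 / a)^2 * a - s * x2,
          cap * w * (1 - x2 / (2 * b)) + s * x1)
  }
  dv <- function(xi, tau) {
    x1 <- xi[, 1L]; x2 <- xi[, 2L]
    qp <- pmax(0, 1 - (x1 / a)^2 - (x2 / b)^2)
    w <- qp^2
    dw1 <- 2 * qp * (-2 * x1 / a^2)
    dw2 <- 2 * qp * (-2 * x2 / b^2)
    s <- csw * w * (1 - w)
    ds1 <- csw * (1 - 2 * w) * dw1
    ds2 <- csw * (1 - 2 * w) * dw2
    g <- 1 - x2 / (2 * b)
    # v1 = cpd * w * x1^2 / a - s * x2 ; v2 = cap * w * g + s * x1
    d11 <- cpd * (dw1 * x1^2 + w * 2 * x1) / a - ds1 * x2
    d12 <- cpd * dw2 * x1^2 / a - ds2 * x2 - s
    d21 <- cap * dw1 * g + ds1 * x1 + s
    d22 <- cap * (dw2 * g - w / (2 * b)) + ds2 * x1
    cbind(d11, d21, d12, d22)
  }
  structure(list(v = v, dv = dv,
                 params = list(ap_asymmetry = ap_asymmetry,
                               pd_nonuniformity = pd_nonuniformity,
                               boundary_swirl = boundary_swirl),
                 semi_axes = semi_axes),
            class = "archetype_flow")
}

#' Add a species-specific divergence to a flow
#'
#' After common time `onset` the perturbation field is ramped in linearly
#' over `ramp` time units, modelling a species whose tissue dynamics depart
#' from the archetype from a given developmental phase onward.
#'
#' @param flow An `archetype_flow` (or any flow list with `v`, `dv`).
#' @param field Perturbation flow (same interface); see
#'   [flow_reverse_ap()] and [flow_proximal()] for built-ins.
#' @param onset Common time at which the divergence starts.
#' @param ramp Time over which the perturbation reaches full strength.
#' @return A flow list combining both fields.
#' @export
flow_with_divergence <- function(flow, field, onset, ramp = 0.05) {
  rampf <- function(tau) pmin(1, pmax(0, (tau - onset) / ramp))
  structure(list(
    v = function(xi, tau) flow$v(xi, tau) + rampf(tau) * field$v(xi, tau),
    dv = function(xi, tau) flow$dv(xi, tau) + rampf(tau) * field$dv(xi, tau),
    params = flow$params, semi_axes = flow$semi_axes,
    divergence_onset = onset
  ), class = class(flow))
}

#' Built-in perturbation fields
#'
#' `flow_reverse_ap()` is a posterior-directed drift (opposing the archetype's
#' A-P asymmetry); `flow_proximal()` is a swirl confined to the proximal part
#' of the bud (xi1 below `edge`), leaving the distal region untouched. Both
#' vanish on the bounding ellipse.
#'
#' @param strength Field strength.
#' @param semi_axes Bump-factor semi-axes.
#' @return A flow list with `v` and `dv`.
#' @export
flow_reverse_ap <- function(strength = 0.5, semi_axes = c(1.05, 0.75)) {
  a <- semi_axes[1L]; b <- semi_axes[2L]
  structure(list(
    v = function(xi, tau) {
      w <- pmax(0, 1 - (xi[, 1L] / a)^2 - (xi[, 2L] / b)^2)^2
      cbind(0 * w, -strength * w)
    },
    dv = function(xi, tau) {
      qp <- pmax(0, 1 - (xi[, 1L] / a)^2 - (xi[, 2L] / b)^2)
      dw1 <- 2 * qp * (-2 * xi[, 1L] / a^2)
      dw2 <- 2 * qp * (-2 * xi[, 2L] / b^2)
      cbind(0 * qp, -strength * dw1, 0 * qp, -strength * dw2)
    }
  ), class = "flow_field")
}

#' @rdname flow_reverse_ap
#' @param edge Proximal boundary (xi1 value) below which the field acts.
#' @param width Smoothing width of the proximal weight.
#' @export
flow_proximal <- function(strength = 0.6, edge = -0.2, width = 0.25,
                          semi_axes = c(1.05, 0.75)) {
  a <- semi_axes[1L]; b <- semi_axes[2L]
  # smooth C1 weight: u = h^2 with h = max(0, (edge - xi1)/width)
  structure(list(
    v = function(xi, tau) {
      w <- pmax(0, 1 - (xi[, 1L] / a)^2 - (xi[, 2L] / b)^2)^2
      h <- pmax(0, (edge - xi[, 1L]) / width)
      u <- h^2
      cbind(-strength * w * u * xi[, 2L], strength * w * u * xi[, 1L])
    },
    dv = function(xi, tau) {
      x1 <- xi[, 1L]; x2 <- xi[, 2L]
      qp <- pmax(0, 1 - (x1 / a)^2 - (x2 / b)^2)
      w <- qp^2
      dw1 <- 2 * qp * (-2 * x1 / a^2)
      dw2 <- 2 * qp * (-2 * x2 / b^2)
      h <- pmax(0, (edge - x1) / width)
      u <- h^2
      du1 <- -2 * h / width
      q <- w * u
      dq1 <- dw1 * u + w * du1
      dq2 <- dw2 * u
      cbind(-strength * (dq1 * x2),
            strength * (dq1 * x1 + q),
            -strength * (dq2 * x2 + q),
            strength * dq2 * x1)
    }
  ), class = "flow_field")
}

#' Species specification for the generator
#'
#' @param name Species label.
#' @param C0 Initial centroid size, micrometres.
#' @param growth_rates Exponential growth rates (per common-time unit) along
#'   P-D and A-P: `L(tau) = C0 R(omega tau') diag(exp(g1 tau'), exp(g2 tau'))`.
#' @param growth_rotation Rotation rate omega (radians per common-time unit).
#' @param centroid_drift Drift of the tissue centre, micrometres per
#'   common-time unit.
#' @param warp Linear stage warp `c(a, b)`: species stage t = a * tau + b.
#' @param outline_xi Initial outline in xi0 units (unit centroid size);
#'   default [reference_outline_xi()].
#' @param tau_span Common-time span simulated.
#' @param n_steps RK4 steps over the full span (default 200).
#' @return Object of class `species_spec`.
#' @export
species_spec <- function(name, C0, growth_rates = c(0.8, 0.5),
                         growth_rotation = 0, centroid_drift = c(0, 0),
                         warp = c(1, 0), outline_xi = NULL,
                         tau_span = c(0, 1), n_steps = 200L) {
  if (warp[1L] <= 0) abort("stage warp must be strictly increasing", class = "morphodyn_value_error")
  structure(list(name = name, C0 = C0, growth_rates = growth_rates,
                 growth_rotation = growth_rotation,
                 centroid_drift = centroid_drift, warp = warp,
                 outline_xi = outline_xi %||% reference_outline_xi(),
                 tau_span = tau_span, n_steps = n_steps),
            class = "species_spec")
}

#' Ground-truth deformation map of a synthetic species
#'
#' Builds `phi(X, t) = L(tau) xi(xi0, tau) + xbar(tau)` with `xi0 = X / C0`,
#' the flow integrated by fixed-step RK4, `tau = (t - b)/a` the common time
#' recovered through the species' stage warp, and `xbar` the prescribed
#' centroid path. The recombination identity holds by construction.
#'
#' @param flow An `archetype_flow`, possibly with divergence.
#' @param spec A [species_spec()].
#' @return A `synthetic_map` (class `deformation_map`) carrying its initial
#'   [tissue_outline()].
#' @export
make_species <- function(flow, spec) {
  tau0 <- spec$tau_span[1L]
  g <- spec$growth_rates; om <- spec$growth_rotation
  L_fn <- function(tau) {
    dtau <- tau - tau0
    spec$C0 * rot2(om * dtau) %*% diag(exp(g * dtau))
  }
  xbar_fn <- function(tau) spec$centroid_drift * (tau - tau0)
  ring_um <- spec$outline_xi * spec$C0
  structure(list(
    flow = flow, C0 = spec$C0, L_fn = L_fn, xbar_fn = xbar_fn,
    warp = spec$warp, tau_span = spec$tau_span, n_steps = spec$n_steps,
    outline = tissue_outline(ring_um, stage = spec$warp[1L] * tau0 + spec$warp[2L]),
    species = spec$name
  ), class = c("synthetic_map", "deformation_map"))
}

#' Measurement design for synthetic labeled-spot data
#'
#' Emulates the integration of several individuals, each observed over a
#' window of consecutive stage intervals with a controlled number of labeled
#' spots, so the per-interval pair counts equal `interval_counts` exactly.
#' With 9 intervals the default design uses 11 individuals: one per interval
#' plus two individuals whose windows span intervals 2-3 and 6-7.
#'
#' @param interval_counts Target pair count per interval.
#' @param noise_sigma Isotropic Gaussian position noise per measurement,
#'   micrometres.
#' @param shared Number of spots contributed by each two-interval individual.
#' @param seed Integer seed: fixed seed gives bit-identical output.
#' @return Object of class `measurement_design`.
#' @export
measurement_design <- function(interval_counts = c(113, 185, 67, 79, 226, 333, 256, 129, 270),
                               noise_sigma = 10, shared = 20L, seed = 1L) {
  K <- length(interval_counts)
  windows <- lapply(seq_len(K), function(k) c(k, k))
  counts <- as.integer(interval_counts)
  if (K >= 7L) {
    windows <- c(windows, list(c(2L, 3L), c(6L, 7L)))
    counts[c(2L, 3L, 6L, 7L)] <- counts[c(2L, 3L, 6L, 7L)] - shared
    counts <- c(counts, shared, shared)
  }
  if (any(counts < 3L)) abort("interval counts too small for the design", class = "morphodyn_value_error")
  structure(list(windows = windows, counts = counts,
                 interval_counts = as.integer(interval_counts),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "measurement_design")
}

#' Sample noisy labeled-spot records from a ground-truth map
#'
#' For each designed individual, seeds quasi-gridded spots (lattice plus
#' jitter) inside the tissue outline advected to the individual's first
#' measurement stage, advects them along the true map to each measurement
#' stage (the stage-grid boundaries its window covers), and adds iid
#' isotropic Gaussian noise per measurement.
#'
#' @param map A ground-truth deformation map.
#' @param design A [measurement_design()].
#' @param grid A [stage_grid()] whose consecutive stages delimit the
#'   intervals of the design.
#' @return A spot tibble (see [read_spot_table()]), sorted by individual,
#'   spot and stage.
#' @export
sample_spots <- function(map, design, grid) {
  bounds <- grid$stages
  set.seed(design$seed)
  ring0 <- outline_ring(initial_outline(map))
  all <- list()
  for (i in seq_along(design$windows)) {
    w <- design$windows[[i]]
    n_spots <- design$counts[i]
    t_meas <- bounds[w[1L]:(w[2L] + 1L)]
    # spots seeded at the window's first stage, inside the advected outline
    ring_t <- evaluate_map(map, ring0, t_meas[1L])
    area <- poly_area(ring_t)
    spacing <- sqrt(area / (2.2 * n_spots))
    lat <- lattice_in_polygon(sweep(ring_t, 2L, poly_centroid(ring_t)), spacing)
    pts <- sweep(cbind(lat$x, lat$y), 2L, poly_centroid(ring_t), "+")
    if (nrow(pts) < n_spots) {
      spacing <- spacing * sqrt(nrow(pts) / n_spots) * 0.9
      lat <- lattice_in_polygon(sweep(ring_t, 2L, poly_centroid(ring_t)), spacing)
      pts <- sweep(cbind(lat$x, lat$y), 2L, poly_centroid(ring_t), "+")
    }
    pts <- pts[sample.int(nrow(pts), n_spots), , drop = FALSE]
    pts <- pts + matrix(stats::runif(2L * n_spots, -0.2, 0.2) * spacing, n_spots, 2L)
    # advect seeds through all measurement stages
    pos <- advect_trajectory(map, pts, t_meas)
    for (s in seq_along(t_meas)) {
      noisy <- pos[, , s] + design$noise_sigma * matrix(stats::rnorm(2L * n_spots), n_spots, 2L)
      all[[length(all) + 1L]] <- tibble::tibble(
        individual_id = sprintf("ind%02d", i),
        stage = t_meas[s],
        spot_id = sprintf("s%03d", seq_len(n_spots)),
        pd_um = noisy[, 1L], ap_um = noisy[, 2L]
      )
    }
  }
  out <- dplyr::bind_rows(all)
  dplyr::arrange(out, .data$individual_id, .data$spot_id, .data$stage)
}

# positions of points given at t_from, at each stage of t_seq (t_seq[1] = t_from)
advect_trajectory <- function(map, pts, t_seq) {
  X0 <- invert_map(map, pts, t_seq[1L])
  map_trajectory(map, X0, t_seq)
}

#' Default two-species scenario
#'
#' A pair of ground-truth species sharing one archetype flow: a small
#' frog-like species (C0 = 400 um, stages 50.6-54.4 over 9 intervals) and a
#' larger chick-like species (C0 = 800 um, stages 21-30.5), whose stage warp
#' between the two scales is linear. Optional flow divergence after a common
#' time and an optional species-B-specific outline.
#'
#' @param flow Archetype flow; default [archetype_flow()] defaults.
#' @param C0 Centroid sizes `c(A, B)` in micrometres.
#' @param warp_b Species-B stage warp `c(a, b)` over common time tau in
#'   [0, 1]; default maps to stages 21-30.5.
#' @param divergence_b Optional list(field, onset, ramp) applied to species
#'   B's flow.
#' @param n_steps RK4 steps.
#' @return List with elements `flow`, `map_a`, `map_b`, `grid_a` (the 9
#'   interval boundaries), `spec_a`, `spec_b`.
#' @export
two_species_scenario <- function(flow = archetype_flow(),
                                 C0 = c(400, 800),
                                 warp_b = c(9.5, 21),
                                 divergence_b = NULL,
                                 n_steps = 200L) {
  spec_a <- species_spec("frog", C0 = C0[1L], growth_rates = c(0.8, 0.5),
                         warp = c(3.8, 50.6), n_steps = n_steps)
  flow_b <- flow
  if (!is.null(divergence_b)) {
    flow_b <- flow_with_divergence(flow, divergence_b$field,
                                   onset = divergence_b$onset,
                                   ramp = divergence_b$ramp %||% 0.05)
  }
  spec_b <- species_spec("chick", C0 = C0[2L], growth_rates = c(0.8, 0.5),
                         warp = warp_b, n_steps = n_steps)
  list(flow = flow,
       map_a = make_species(flow, spec_a),
       map_b = make_species(flow_b, spec_b),
       grid_a = stage_grid("frog", seq(50.6, 54.4, length.out = 10L)),
       grid_b = stage_grid("chick", seq(warp_b[2L], warp_b[1L] + warp_b[2L], length.out = 10L)),
       spec_a = spec_a, spec_b = spec_b)
}

#' Band-localized anterior drift flow
#'
#' An archetype-flow variant whose only motion is an anterior-directed drift
#' confined to a Gaussian band of P-D positions. Orientation information in
#' the rescaled dynamics then lives in that band: a sub-region that excludes
#' it has essentially featureless dynamics, the construction used to study
#' overfitting of the region-axis angle.
#'
#' @param strength Drift strength.
#' @param center,width Centre and width of the Gaussian band in xi1.
#' @param semi_axes Bump-factor semi-axes.
#' @return A flow list with `v` and `dv`.
#' @export
flow_band_drift <- function(strength = 1.2, center = -0.3, width = 0.1,
                            semi_axes = c(1.05, 0.75)) {
  a <- semi_axes[1L]; b <- semi_axes[2L]
  structure(list(
    v = function(xi, tau) {
      x1 <- xi[, 1L]; x2 <- xi[, 2L]
      w <- pmax(0, 1 - (x1 / a)^2 - (x2 / b)^2)^2
      B <- exp(-((x1 - center) / width)^2)
      cbind(0 * w, strength * w * B)
    },
    dv = function(xi, tau) {
      x1 <- xi[, 1L]; x2 <- xi[, 2L]
      qp <- pmax(0, 1 - (x1 / a)^2 - (x2 / b)^2)
      w <- qp^2
      dw1 <- 2 * qp * (-2 * x1 / a^2)
      dw2 <- 2 * qp * (-2 * x2 / b^2)
      B <- exp(-((x1 - center) / width)^2)
      dB <- B * (-2 * (x1 - center) / width^2)
      cbind(0 * w, strength * (dw1 * B + w * dB), 0 * w, strength * dw2 * B)
    }
  ), class = "flow_field")
}

#' @rdname flow_band_drift
#' @details `flow_proximal_reversal()` is a posterior-directed drift confined
#'   to the proximal side (`xi1 < edge`, smooth C1 onset), used to plant a
#'   species-specific divergence in the prospective stylopod territory.
#' @param edge Proximal boundary in xi1.
#' @export
flow_proximal_reversal <- function(strength = 2, edge = -0.5, width = 0.15,
                                   semi_axes = c(1.05, 0.75)) {
  a <- semi_axes[1L]; b <- semi_axes[2L]
  structure(list(
    v = function(xi, tau) {
      x1 <- xi[, 1L]; x2 <- xi[, 2L]
      w <- pmax(0, 1 - (x1 / a)^2 - (x2 / b)^2)^2
      h <- pmax(0, (edge - x1) / width)
      cbind(0 * w, -strength * w * h^2)
    },
    dv = function(xi, tau) {
      x1 <- xi[, 1L]; x2 <- xi[, 2L]
      qp <- pmax(0, 1 - (x1 / a)^2 - (x2 / b)^2)
      w <- qp^2
      dw1 <- 2 * qp * (-2 * x1 / a^2)
      dw2 <- 2 * qp * (-2 * x2 / b^2)
      h <- pmax(0, (edge - x1) / width)
      du1 <- -2 * h / width
      cbind(0 * w, -strength * (dw1 * h^2 + w * du1), 0 * w, -strength * dw2 * h^2)
    }
  ), class = "flow_field")
}

#' Planted region-conservation scenario
#'
#' Builds a species pair whose rescaled dynamics agree exactly on the distal
#' fraction `alpha_true` of species X's bud, cut along a P-D axis rotated by
#' `theta_true`: species C is a scaled, rotated copy of species X restricted
#' to the conserved region (so the restricted-X system at the true
#' parameters is identical to C's by construction), while X additionally
#' carries a proximal swirl perturbation outside the region (the prospective
#' stylopod territory whose dynamics are species specific).
#'
#' @param alpha_true Conserved distal fraction.
#' @param theta_true Planted region-axis rotation (radians).
#' @param C0 Species X centroid size, micrometres.
#' @param scale_c Size ratio of species C over X.
#' @param flow Archetype flow shared inside the conserved region.
#' @param divergence_strength Proximal perturbation strength.
#' @param n_steps RK4 steps.
#' @return List with `map_x`, `ring_x`, `map_c`, `outline_c`,
#'   `region_true` and the planted parameters.
#' @export
region_recovery_scenario <- function(alpha_true = 0.7, theta_true = 0.3,
                                     C0 = 400, scale_c = 2,
                                     flow = archetype_flow(ap_asymmetry = 1.1,
                                                           pd_nonuniformity = 0.65,
                                                           boundary_swirl = 0.35),
                                     divergence_strength = 3,
                                     n_steps = 80L) {
  ring_xi <- reference_outline_xi()
  reg_xi <- outline_ring(region_from_params(ring_xi, alpha_true, 0, theta_true))
  pert <- flow_proximal(strength = divergence_strength,
                        edge = min(reg_xi[, 1L]) - 0.02, width = 0.25)
  flow_x <- flow_with_divergence(flow, pert, onset = 0, ramp = 0.02)
  map_x <- make_species(flow_x, species_spec("X", C0 = C0, warp = c(1, 0),
                                             n_steps = n_steps))
  ring_x <- outline_ring(initial_outline(map_x))
  reg_um <- outline_ring(region_from_params(ring_x, alpha_true, 0, theta_true))
  outline_c <- tissue_outline(scale_c * reg_um %*% rot2(theta_true))
  map_c <- conjugate_map(map_x, scale = scale_c, warp = c(1, 0),
                         rotation = -theta_true, outline = outline_c)
  list(map_x = map_x, ring_x = ring_x, map_c = map_c, outline_c = outline_c,
       region_true = reg_um, alpha_true = alpha_true, theta_true = theta_true)
}
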