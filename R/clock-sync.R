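# Developmental-clock synchronization between two species: distances between
# xi-trajectory snapshots over a shared seed set, the stage-pair distance
# matrix, composite stage maps (per-row/column argmins), their homeomorphism
# validity range, and the linear stage correspondence.

# Comparison-frame helpers: a xi_dynamics object may carry a rigid chart
# change (A-P offset beta, rotation theta) installed by restrict_dynamics().
xi_frame <- function(dyn) dyn$frame %||% list(beta = 0, theta = 0)

xi_frame_fwd <- function(dyn, xi) {
  fr <- xi_frame(dyn)
  if (fr$beta == 0 && fr$theta == 0) return(xi)
  sweep(xi, 2L, c(0, fr$beta)) %*% rot2(fr$theta)   # (xi - b) %*% R(-theta)^T
}

xi_frame_inv <- function(dyn, xi) {
  fr <- xi_frame(dyn)
  if (fr$beta == 0 && fr$theta == 0) return(xi)
  sweep(xi %*% rot2(-fr$theta), 2L, c(0, fr$beta), "+")
}

# xi snapshots of a dynamics object at seeds given in the comparison frame.
# When the frame is trivial and the request lies on the stored seed lattice
# and stage grid, stored trajectories are indexed instead of re-evaluating
# the map.
xi_compare_traj <- function(dyn, omega_xi, stages) {
  omega_xi <- as_points(omega_xi)
  fr <- xi_frame(dyn)
  if (fr$beta == 0 && fr$theta == 0) {
    si <- match(round(stages, 10L), round(dyn$stages, 10L))
    ki <- round(omega_xi / dyn$spacing)
    on_lat <- max(abs(omega_xi - ki * dyn$spacing)) < 1e-9 * dyn$spacing
    if (!anyNA(si) && on_lat) {
      pos <- match(paste(ki[, 1L], ki[, 2L]),
                   paste(dyn$seeds$ix, dyn$seeds$iy))
      if (!anyNA(pos)) {
        return(dyn$traj[pos, , si, drop = FALSE])
      }
    }
  }
  xi0 <- xi_frame_inv(dyn, omega_xi)
  tr <- xi_at(dyn, xi0, stages)
  for (s in seq_along(stages)) tr[, , s] <- xi_frame_fwd(dyn, slice3(tr, s))
  tr
}

outline_in_frame <- function(dyn) xi_frame_fwd(dyn, dyn$outline_xi)

#' Overlap seed set of two species in xi space
#'
#' Intersects both species' initial outlines in the (comparison-frame)
#' dimensionless xi0 coordinates and returns the regular lattice points
#' inside the intersection. These seeds index the shared trajectories over
#' which stage-pair distances are averaged.
#'
#' @param dyn_a,dyn_b `xi_dynamics` objects.
#' @param spacing Lattice spacing; default the finer of the two stored
#'   spacings.
#' @param shrink Factor in (0, 1] scaling both outlines toward their
#'   centroids before intersecting. Values below 1 restrict the seeds to the
#'   internal tissue, whose trajectories carry the cross-species signal,
#'   excluding the boundary layer where the flows shape each species' own
#'   contour (and where fitted maps are least constrained by data).
#' @return Tibble with columns `xi0_pd`, `xi0_ap`.
#' @export
overlap_region <- function(dyn_a, dyn_b, spacing = NULL, shrink = 1) {
  spacing <- spacing %||% min(dyn_a$spacing, dyn_b$spacing)
  erode <- function(ring) {
    if (shrink >= 1) return(ring)
    ctr <- poly_centroid(ring)
    sweep(sweep(ring, 2L, ctr) * shrink, 2L, ctr, "+")
  }
  ring_a <- erode(outline_in_frame(dyn_a))
  ring_b <- erode(outline_in_frame(dyn_b))
  lat <- lattice_in_polygon(ring_a, spacing)
  if (nrow(lat) > 0L) {
    keep <- points_in_poly(cbind(lat$x, lat$y), ring_b)
    lat <- lat[keep, , drop = FALSE]
  }
  if (nrow(lat) == 0L) {
    abort("the two outlines do not overlap in xi space", class = "morphodyn_overlap_error")
  }
  tibble::tibble(xi0_pd = lat$x, xi0_ap = lat$y)
}

#' Distance between two species' rescaled snapshots at a stage pair
#'
#' Mean Euclidean distance, over the shared seed set, between the rescaled
#' positions of the two species at stages `t_a` and `t_b` on trajectories
#' started from the same dimensionless seed.
#'
#' @param dyn_a,dyn_b `xi_dynamics` objects.
#' @param t_a,t_b Stages on each species' own scale.
#' @param omega Optional seed tibble from [overlap_region()].
#' @return Dimensionless scalar distance.
#' @export
trajectory_distance <- function(dyn_a, dyn_b, t_a, t_b, omega = NULL) {
  omega <- omega %||% overlap_region(dyn_a, dyn_b)
  seeds <- cbind(omega$xi0_pd, omega$xi0_ap)
  xa <- slice3(xi_compare_traj(dyn_a, seeds, t_a), 1L)
  xb <- slice3(xi_compare_traj(dyn_b, seeds, t_b), 1L)
  if (is.null(dim(xa))) { xa <- matrix(xa, ncol = 2L); xb <- matrix(xb, ncol = 2L) }
  mean(sqrt(rowSums((xa - xb)^2)))
}

#' Stage-pair distance matrix between two species
#'
#' Evaluates the trajectory distance over the full product of the two stage
#' grids, the raw material for clock synchronization.
#'
#' @param dyn_a,dyn_b `xi_dynamics` objects.
#' @param stages_a,stages_b Stage grids; default each decomposition's grid.
#' @param omega Optional seed tibble from [overlap_region()].
#' @return Object of class `stage_distance` with the matrix `delta`
#'   (rows = species A stages, columns = species B stages).
#' @export
distance_matrix <- function(dyn_a, dyn_b, stages_a = NULL, stages_b = NULL,
                            omega = NULL) {
  stages_a <- stages_a %||% dyn_a$stages
  stages_b <- stages_b %||% dyn_b$stages
  omega <- omega %||% overlap_region(dyn_a, dyn_b)
  seeds <- cbind(omega$xi0_pd, omega$xi0_ap)
  xa <- xi_compare_traj(dyn_a, seeds, stages_a)
  xb <- xi_compare_traj(dyn_b, seeds, stages_b)
  delta <- matrix(NA_real_, length(stages_a), length(stages_b))
  for (i in seq_along(stages_a)) {
    for (j in seq_along(stages_b)) {
      delta[i, j] <- mean(sqrt(rowSums((xa[, , i] - xb[, , j])^2)))
    }
  }
  structure(list(delta = delta, stages_a = stages_a, stages_b = stages_b,
                 omega = omega,
                 species_a = dyn_a$species %||% "A",
                 species_b = dyn_b$species %||% "B"),
            class = "stage_distance")
}

#' @export
print.stage_distance <- function(x, ...) {
  cat("<stage_distance> ", x$species_a, " (", length(x$stages_a), " stages) x ",
      x$species_b, " (", length(x$stages_b), " stages), ",
      nrow(x$omega), " shared seeds\n", sep = "")
  invisible(x)
}

#' Composite stage maps from a distance matrix
#'
#' For each stage of one species, the closest stage of the other (the row- or
#' column-wise argmin of the distance matrix); ties are broken toward the
#' earlier stage. Both directions are returned.
#'
#' @param dm A `stage_distance` object.
#' @return List with elements `ab` and `ba`, each a tibble of class
#'   `stage_map` with columns `t_source`, `t_target`, `target_index`,
#'   `delta_min`.
#' @export
composite_stage_maps <- function(dm) {
  stopifnot(inherits(dm, "stage_distance"))
  ab <- tibble::tibble(
    t_source = dm$stages_a,
    target_index = apply(dm$delta, 1L, which.min),
    delta_min = apply(dm$delta, 1L, min)
  )
  ab$t_target <- dm$stages_b[ab$target_index]
  ab$t_target_refined <- refine_argmin(dm$delta, ab$target_index, dm$stages_b,
                                       by_row = TRUE)
  ba <- tibble::tibble(
    t_source = dm$stages_b,
    target_index = apply(dm$delta, 2L, which.min),
    delta_min = apply(dm$delta, 2L, min)
  )
  ba$t_target <- dm$stages_a[ba$target_index]
  ba$t_target_refined <- refine_argmin(dm$delta, ba$target_index, dm$stages_a,
                                       by_row = FALSE)
  ab <- structure(ab, direction = paste0(dm$species_a, "->", dm$species_b),
                  class = c("stage_map", class(ab)))
  ba <- structure(ba, direction = paste0(dm$species_b, "->", dm$species_a),
                  class = c("stage_map", class(ba)))
  list(ab = ab, ba = ba)
}

# sub-grid refinement of the discrete argmin by a parabola through the
# minimum and its two neighbours (falls back to the grid stage at the ends)
refine_argmin <- function(delta, idx, stages, by_row = TRUE) {
  n <- length(idx)
  out <- stages[idx]
  m <- length(stages)
  for (k in seq_len(n)) {
    j <- idx[k]
    if (j <= 1L || j >= m) next
    f0 <- if (by_row) delta[k, j - 1L] else delta[j - 1L, k]
    f1 <- if (by_row) delta[k, j] else delta[j, k]
    f2 <- if (by_row) delta[k, j + 1L] else delta[j + 1L, k]
    denom <- f0 - 2 * f1 + f2
    if (denom > 0) {
      shift <- 0.5 * (f0 - f2) / denom
      shift <- max(-0.5, min(0.5, shift))
      out[k] <- stages[j] + shift * (stages[j + 1L] - stages[j])
    }
  }
  out
}

#' Validity range of the composite stage maps
#'
#' The synchronization is meaningful only while the stage correspondence is a
#' homeomorphism: strictly monotone, without jumps larger than `tol` grid
#' steps, and with the two directions mutually inverse within `tol` steps.
#' Returns the largest initial segment on which all three conditions hold.
#'
#' @param maps Result of [composite_stage_maps()].
#' @param tol Tolerance in grid steps (default 1).
#' @return List with `t_a_end`, `t_b_end` (last valid source stages of each
#'   direction) and the per-stage validity flags.
#' @export
validity_range <- function(maps, tol = 1L) {
  ab <- maps$ab; ba <- maps$ba
  check_dir <- function(fwd, bwd) {
    m <- nrow(fwd)
    ok <- rep(TRUE, m)
    for (k in seq_len(m)) {
      if (k > 1L) {
        jump <- fwd$target_index[k] - fwd$target_index[k - 1L]
        if (jump < 1L || jump > tol) ok[k] <- FALSE
      }
      back <- bwd$target_index[fwd$target_index[k]]
      if (abs(back - k) > tol) ok[k] <- FALSE
    }
    ok
  }
  ok_a <- check_dir(ab, ba)
  ok_b <- check_dir(ba, ab)
  run_end <- function(ok) {
    bad <- which(!ok)
    if (length(bad) == 0L) length(ok) else bad[1L] - 1L
  }
  ka <- run_end(ok_a); kb <- run_end(ok_b)
  list(
    t_a_end = if (ka >= 1L) ab$t_source[ka] else NA_real_,
    t_b_end = if (kb >= 1L) ba$t_source[kb] else NA_real_,
    k_a = ka, k_b = kb, ok_a = ok_a, ok_b = ok_b
  )
}

#' Linear fit of a composite stage map
#'
#' Least-squares line `t_target ~ t_source` over the pairs inside `range`,
#' reporting the maximum absolute residual.
#'
#' @param map A `stage_map` tibble.
#' @param range Optional `c(lo, hi)` restriction on `t_source`.
#' @return Tibble of class `stage_linear_fit` with columns `slope`,
#'   `intercept`, `max_residual`, `n`.
#' @export
fit_linear_correspondence <- function(map, range = NULL) {
  d <- map
  if (!is.null(range)) d <- d[d$t_source >= range[1L] & d$t_source <= range[2L], ]
  if (nrow(d) < 3L) abort("need at least 3 stage pairs", class = "morphodyn_value_error")
  if (!is.null(d[["t_target_refined"]])) d$t_target <- d[["t_target_refined"]]
  fit <- stats::lm(t_target ~ t_source, data = d)
  out <- tibble::tibble(slope = unname(stats::coef(fit)[2L]),
                        intercept = unname(stats::coef(fit)[1L]),
                        max_residual = max(abs(stats::residuals(fit))),
                        n = nrow(d))
  class(out) <- c("stage_linear_fit", class(out))
  out
}

#' Choose the best-matching pair of initial stages
#'
#' Re-references species B's map to each candidate initial stage, compares it
#' with region-restricted species-A dynamics for every configured (alpha,
#' beta) parameter set (minimizing the trajectory-difference statistic eta
#' over the theta grid), and reports per-candidate median and standard
#' deviation of those minima. The best candidate has the lowest median.
#'
#' @param map_a,map_b Deformation maps of the two species.
#' @param outline_a,outline_b Their initial outlines.
#' @param candidates_b Candidate initial stages for species B.
#' @param paramsets Data frame with columns `alpha`, `beta`: the region
#'   parameter sets over which robustness is assessed.
#' @param theta_grid Axis-rotation grid over which eta is minimized.
#' @param period Optional `c(lo, hi)` species-A stage window for eta.
#' @param n_stages Decomposition stage-grid size.
#' @param ... Further arguments passed to [decompose()] (e.g. `n_quad`,
#'   `seed_spacing`).
#' @return Tibble with columns `t0_b`, `median_eta`, `sd_eta`; the winning
#'   candidate is in attribute `best`.
#' @export
select_initial_stages <- function(map_a, outline_a, map_b, outline_b,
                                  candidates_b, paramsets, theta_grid,
                                  period = NULL, n_stages = 11L, ...) {
  # region-restricted A dynamics do not depend on the candidate: cache them
  combos <- tidyr::expand_grid(set = seq_len(nrow(paramsets)), theta = theta_grid)
  rng_a <- map_stage_range(map_a)
  stages_a <- seq(rng_a[1L], rng_a[2L], length.out = n_stages)
  dyn_a_list <- purrr::pmap(combos, function(set, theta) {
    restrict_dynamics(map_a, outline_a, alpha = paramsets$alpha[set],
                      beta = paramsets$beta[set], theta = theta,
                      stages = stages_a, ...)
  })
  res <- purrr::map_dfr(candidates_b, function(t0b) {
    mb <- if (abs(t0b - map_stage_range(map_b)[1L]) < 1e-9) map_b else
      rebase_map(map_b, t0b, outline = NULL)
    rng_b <- map_stage_range(mb)
    stages_b <- seq(rng_b[1L], rng_b[2L], length.out = n_stages)
    dyn_b <- decompose(mb, outline = initial_outline(mb) %||% outline_b,
                       stages = stages_b, ...)$xi
    mins <- vapply(seq_len(nrow(paramsets)), function(set) {
      vals <- vapply(which(combos$set == set), function(i) {
        eta(dyn_a_list[[i]], dyn_b, period = period)
      }, numeric(1L))
      min(vals)
    }, numeric(1L))
    tibble::tibble(t0_b = t0b, median_eta = stats::median(mins),
                   sd_eta = stats::sd(mins))
  })
  attr(res, "best") <- res$t0_b[which.min(res$median_eta)]
  res
}
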