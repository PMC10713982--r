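# Region-restricted cross-species comparison: parameterize a candidate
# sub-region of one species' limb bud (distal extent alpha along a P-D axis
# rotated by theta, with the comparison frame offset beta along A-P),
# recompute the rescaled dynamics on the sub-region, and quantify agreement
# (eta) and overfitting (CV of the optimal theta across beta).

#' Candidate sub-region of an outline
#'
#' Cuts the outline to the distal fraction `alpha` of its extent measured
#' along a P-D axis: the line through the outline centroid, offset by `beta`
#' (dimensionless xi units) in the antero-posterior direction and rotated by
#' `theta`. The extent is the chord of that axis line inside the outline, so
#' the offset and rotation genuinely change which tissue is retained; the cut
#' itself is a half-plane clip perpendicular to the axis. `alpha = 1` with
#' `beta = 0` returns the full outline.
#'
#' @param outline A [tissue_outline()] or vertex ring (micrometres).
#' @param alpha Distal fraction retained, in (0, 1].
#' @param beta A-P offset of the axis origin, xi units (scaled by the
#'   outline's centroid size).
#' @param theta Axis rotation in radians, in (-pi/2, pi/2].
#' @return A [tissue_outline()] of the clipped region.
#' @export
region_from_params <- function(outline, alpha, beta = 0, theta = 0) {
  if (!(alpha > 0 && alpha <= 1)) abort("alpha must be in (0, 1]", class = "morphodyn_value_error")
  if (!(theta > -pi / 2 && theta <= pi / 2)) {
    abort("theta must be in (-pi/2, pi/2]", class = "morphodyn_value_error")
  }
  ring <- outline_ring(outline)
  if (alpha == 1 && beta == 0) return(tissue_outline(ring))
  u <- c(cos(theta), sin(theta))           # P-D axis direction, distal positive
  nrm <- c(-sin(theta), cos(theta))        # A-P direction of the rotated frame
  o <- poly_centroid(ring) + beta * centroid_size(ring) * nrm
  ext <- axis_chord_extent(ring, o, u)
  cut <- ext[2L] - alpha * (ext[2L] - ext[1L])
  clipped <- clip_halfplane(ring, u, sum(o * u) + cut)
  if (is.null(clipped) || poly_area(clipped) <= 0) {
    abort("region clip is empty", class = "morphodyn_empty_region_error")
  }
  tissue_outline(clipped)
}

# s-range (relative to o, along direction u) of the intersections of the
# axis line {o + s u} with the ring
axis_chord_extent <- function(ring, o, u) {
  n <- nrow(ring)
  nrm <- c(-u[2L], u[1L])
  d <- as.numeric(sweep(ring, 2L, o) %*% nrm)
  svals <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if ((d[i] >= 0) != (d[j] >= 0)) {
      tt <- d[i] / (d[i] - d[j])
      pt <- ring[i, ] + tt * (ring[j, ] - ring[i, ])
      svals <- c(svals, sum((pt - o) * u))
    }
  }
  if (length(svals) < 2L) {
    abort("the region axis does not intersect the outline",
          class = "morphodyn_empty_region_error")
  }
  range(svals)
}

#' Rescaled dynamics of a sub-region
#'
#' Recomputes the full decomposition (centroid size, mean growth, centroid
#' path, xi trajectories) on the clipped sub-region, so the restricted system
#' is self-contained, and installs the comparison frame: rescaled positions
#' are offset by `beta` (A-P, dimensionless) and rotated by `-theta` before
#' any cross-species comparison, aligning the region's axis with the partner
#' species' P-D axis.
#'
#' @param map The species' deformation map.
#' @param outline Its full initial outline.
#' @param alpha,beta,theta Region parameters: distal fraction, A-P frame
#'   offset (xi units), axis rotation (radians).
#' @param ... Passed to [decompose()] (`stages`, `n_quad`, `seed_spacing`).
#' @return A `xi_dynamics` object for the restricted system.
#' @export
restrict_dynamics <- function(map, outline, alpha = 1, beta = 0, theta = 0, ...) {
  region <- region_from_params(outline, alpha = alpha, beta = beta, theta = theta)
  dec <- decompose(map, outline = region, ...)
  dyn <- dec$xi
  dyn$frame <- list(beta = 0, theta = theta)
  dyn
}

#' Temporal-average trajectory difference eta
#'
#' For each source-species stage in `period`, finds the closest target-species
#' stage (the argmin over the target grid of the seed-averaged trajectory
#' distance) and averages those minimal distances over the period.
#'
#' @param dyn_source `xi_dynamics` of the source species (possibly
#'   region-restricted).
#' @param dyn_target `xi_dynamics` of the target species.
#' @param period Optional `c(lo, hi)` window of source stages; default all.
#' @param omega Optional seed set from [overlap_region()].
#' @return Dimensionless scalar eta.
#' @export
eta <- function(dyn_source, dyn_target, period = NULL, omega = NULL) {
  stages_s <- dyn_source$stages
  if (!is.null(period)) stages_s <- stages_s[stages_s >= period[1L] & stages_s <= period[2L]]
  if (length(stages_s) == 0L) abort("no source stages in period", class = "morphodyn_value_error")
  dm <- distance_matrix(dyn_source, dyn_target, stages_a = stages_s, omega = omega)
  mean(apply(dm$delta, 1L, min))
}

#' @rdname eta
#' @details `eta_tilde` is the mirrored statistic: the target species supplies
#'   the discretized stages and the source grid is scanned for the argmin
#'   (source/target swapped relative to `eta`), with `period` a window of
#'   target stages.
#' @export
eta_tilde <- function(dyn_source, dyn_target, period = NULL, omega = NULL) {
  stages_t <- dyn_target$stages
  if (!is.null(period)) stages_t <- stages_t[stages_t >= period[1L] & stages_t <= period[2L]]
  if (length(stages_t) == 0L) abort("no target stages in period", class = "morphodyn_value_error")
  dm <- distance_matrix(dyn_source, dyn_target, stages_b = stages_t, omega = omega)
  mean(apply(dm$delta, 2L, min))
}

#' Overfitting statistic: coefficient of variation of theta*
#'
#' Given eta over a (beta, theta) grid at fixed alpha, the optimal rotation
#' theta*(beta) = argmin_theta eta should be stable across beta if the
#' restricted comparison is not overfitted. The statistic is the population
#' coefficient of variation sqrt(Var_beta[theta*]) / E_beta[theta*].
#'
#' @param eta_table Tibble with columns `beta`, `theta`, `eta` (one alpha).
#' @return A one-row tibble with `cv`, `mean_theta_star`, `undefined`
#'   (`TRUE` when the mean of theta* is zero and the CV is not defined).
#' @export
cv_overfit <- function(eta_table) {
  ts <- eta_table |>
    dplyr::group_by(.data$beta) |>
    dplyr::summarise(theta_star = .data$theta[which.min(.data$eta)], .groups = "drop")
  m <- mean(ts$theta_star)
  v <- mean((ts$theta_star - m)^2)          # population variance
  undefined <- abs(m) < .Machine$double.eps
  tibble::tibble(cv = if (undefined) NA_real_ else sqrt(v) / abs(m),
                 mean_theta_star = m, undefined = undefined)
}

#' Scan the conserved distal extent
#'
#' For every alpha on the grid, computes eta over the (beta, theta) grid with
#' the species-A dynamics restricted to the distal fraction alpha, and
#' summarizes the two curves of the region analysis: `min_eta(alpha)` (over
#' beta and theta) and `cv(alpha)` (overfitting of theta*). The compatibility
#' band is the set of alphas where both fall below their thresholds.
#'
#' @param map_source,outline_source Deformation map and initial outline of
#'   the species being restricted.
#' @param dyn_target `xi_dynamics` of the partner species.
#' @param alpha_grid,beta_grid,theta_grid Parameter grids.
#' @param period Optional source-stage window for eta.
#' @param eta_threshold,cv_threshold Compatibility thresholds for the band.
#' @param n_stages Source decomposition stage-grid size.
#' @param ... Passed to [decompose()] via [restrict_dynamics()].
#' @return Object of class `region_scan`: a list with the full `table`
#'   (alpha, beta, theta, eta), the per-alpha `summary` (min_eta, cv,
#'   compatible), and the `band` range (NA if empty).
#' @export
scan_alpha <- function(map_source, outline_source, dyn_target,
                       alpha_grid = seq(0.3, 1, by = 0.05),
                       beta_grid = seq(-0.2, 0.2, length.out = 9L),
                       theta_grid = seq(-pi / 6, pi / 6, length.out = 31L),
                       period = NULL, eta_threshold = Inf, cv_threshold = Inf,
                       n_stages = 11L, ...) {
  rng <- map_stage_range(map_source)
  stages_s <- seq(rng[1L], rng[2L], length.out = n_stages)
  rows <- list()
  for (a in alpha_grid) {
    for (b in beta_grid) {
      for (th in theta_grid) {
        dyn0 <- restrict_dynamics(map_source, outline_source, alpha = a,
                                  beta = b, theta = th, stages = stages_s, ...)
        e <- eta(dyn0, dyn_target, period = period)
        rows[[length(rows) + 1L]] <- tibble::tibble(alpha = a, beta = b,
                                                    theta = th, eta = e)
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  summ <- tab |>
    dplyr::group_by(.data$alpha) |>
    dplyr::group_modify(function(d, key) {
      ov <- cv_overfit(d)
      tibble::tibble(min_eta = min(d$eta), cv = ov$cv,
                     cv_undefined = ov$undefined)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(compatible = .data$min_eta <= eta_threshold &
                    !is.na(.data$cv) & .data$cv <= cv_threshold)
  band <- if (any(summ$compatible)) range(summ$alpha[summ$compatible]) else c(NA_real_, NA_real_)
  structure(list(table = tab, summary = summ, band = band,
                 eta_threshold = eta_threshold, cv_threshold = cv_threshold),
            class = "region_scan")
}

#' @export
print.region_scan <- function(x, ...) {
  cat("<region_scan> ", length(unique(x$table$alpha)), " alphas; band: ",
      if (is.na(x$band[1L])) "empty" else paste(signif(x$band, 3), collapse = " - "),
      "\n", sep = "")
  print(x$summary)
  invisible(x)
}
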