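# broom-style tidiers for the package's fitted objects.

#' @export
tidy.interval_map <- function(x, ...) {
  terms <- character(0)
  for (d in 0:x$degree) for (j in 0:d) {
    terms <- c(terms, sprintf("u%dv%d", d - j, j))
  }
  tibble::tibble(
    term = rep(terms, 2L),
    component = rep(c("pd", "ap"), each = length(terms)),
    estimate = c(x$beta[, 1L], x$beta[, 2L])
  )
}

#' @export
glance.interval_map <- function(x, ...) {
  tibble::tibble(
    interval = x$interval, stage_start = x$stage_start, stage_end = x$stage_end,
    n = x$n, mean_residual = x$mean_residual,
    lengthscale = x$hyp$ell, signal_var = x$hyp$sf2, noise_var = x$hyp$sn2,
    gp = x$use_gp
  )
}

#' @export
glance.fitted_map <- function(x, ...) {
  purrr::map_dfr(x$interval_maps, glance)
}

#' @export
tidy.stage_distance <- function(x, ...) {
  tidyr::expand_grid(t_a = x$stages_a, t_b = x$stages_b) |>
    dplyr::mutate(delta = as.vector(t(x$delta)))
}

#' @export
tidy.stage_map <- function(x, ...) {
  tibble::tibble(t_source = x$t_source, t_target = x$t_target,
                 delta_min = x$delta_min,
                 direction = attr(x, "direction") %||% NA_character_)
}

#' @export
glance.stage_linear_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.scaling_operator <- function(x, ...) {
  tibble::tibble(
    component = c("stretch_major", "stretch_minor", "rotation_rad"),
    value = c(x$stretches[1L], x$stretches[2L], atan2(x$R[2L, 1L], x$R[1L, 1L]))
  )
}

#' @export
tidy.xi_dynamics <- function(x, ...) {
  S <- length(x$stages)
  n <- nrow(x$xi0)
  tibble::tibble(
    seed = rep(seq_len(n), times = S),
    xi0_pd = rep(x$xi0[, 1L], times = S),
    xi0_ap = rep(x$xi0[, 2L], times = S),
    stage = rep(x$stages, each = n),
    xi_pd = as.vector(x$traj[, 1L, ]),
    xi_ap = as.vector(x$traj[, 2L, ])
  )
}

#' @export
tidy.mean_growth <- function(x, ...) {
  S <- length(x$stages)
  tibble::tibble(
    stage = x$stages,
    L11 = x$L[1L, 1L, ], L12 = x$L[1L, 2L, ],
    L21 = x$L[2L, 1L, ], L22 = x$L[2L, 2L, ],
    det_L = x$L[1L, 1L, ] * x$L[2L, 2L, ] - x$L[1L, 2L, ] * x$L[2L, 1L, ],
    xbar_pd = x$xbar[, 1L], xbar_ap = x$xbar[, 2L]
  )
}

#' @export
glance.mean_growth <- function(x, ...) {
  tibble::tibble(C0 = x$C0, n_stages = length(x$stages),
                 stage_min = min(x$stages), stage_max = max(x$stages))
}

#' @export
tidy.region_scan <- function(x, ...) x$table

#' @export
glance.region_scan <- function(x, ...) {
  tibble::tibble(band_lo = x$band[1L], band_hi = x$band[2L],
                 eta_threshold = x$eta_threshold, cv_threshold = x$cv_threshold)
}
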