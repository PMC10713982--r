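#' Deformation map from closed-form functions
#'
#' Wraps user-supplied functions as a deformation map, mainly for analytic
#' test cases and worked examples (e.g. exact affine or separable maps).
#'
#' @param eval_fn Function `(X, t) -> n x 2` positions.
#' @param jac_fn Optional function `(X, t) -> 2 x 2 x n` Jacobians; when
#'   absent, central finite differences with step `fd_step` are used.
#' @param stage_range Length-2 numeric range of valid stages.
#' @param outline Optional initial [tissue_outline()].
#' @param fd_step Finite-difference step in micrometres; default 1e-3 of the
#'   outline diameter (or 1e-3 absolute without an outline).
#' @return Object of class `analytic_map` (also `deformation_map`).
#' @export
analytic_map <- function(eval_fn, jac_fn = NULL, stage_range, outline = NULL,
                         fd_step = NULL) {
  if (is.null(fd_step)) {
    fd_step <- if (!is.null(outline)) {
      ring <- outline_ring(outline)
      1e-3 * sqrt(sum(apply(ring, 2L, function(v) diff(range(v)))^2))
    } else 1e-3
  }
  structure(list(eval_fn = eval_fn, jac_fn = jac_fn,
                 stage_range = as.numeric(stage_range), outline = outline,
                 fd_step = fd_step),
            class = c("analytic_map", "deformation_map"))
}

#' @export
map_stage_range.analytic_map <- function(map) map$stage_range

#' @export
evaluate_map.analytic_map <- function(map, X, t) {
  t <- check_stage(map, t)
  map$eval_fn(as_points(X), t)
}

#' @export
deformation_gradient.analytic_map <- function(map, X, t) {
  X <- as_points(X)
  t <- check_stage(map, t)
  if (!is.null(map$jac_fn)) return(map$jac_fn(X, t))
  h <- map$fd_step
  n <- nrow(X)
  J <- array(NA_real_, dim = c(2L, 2L, n))
  for (d in 1:2) {
    e <- c(0, 0); e[d] <- h
    fp <- map$eval_fn(sweep(X, 2L, e, "+"), t)
    fm <- map$eval_fn(sweep(X, 2L, e), t)
    J[1L, d, ] <- (fp[, 1L] - fm[, 1L]) / (2 * h)
    J[2L, d, ] <- (fp[, 2L] - fm[, 2L]) / (2 * h)
  }
  J
}

#' @export
map_trajectory.deformation_map <- function(map, X, stages) {
  X <- as_points(X)
  out <- array(NA_real_, dim = c(nrow(X), 2L, length(stages)))
  for (s in seq_along(stages)) out[, , s] <- evaluate_map(map, X, stages[s])
  out
}

#' @export
gradient_trajectory.deformation_map <- function(map, X, stages) {
  X <- as_points(X)
  out <- array(NA_real_, dim = c(2L, 2L, nrow(X), length(stages)))
  for (s in seq_along(stages)) out[, , , s] <- deformation_gradient(map, X, stages[s])
  out
}
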