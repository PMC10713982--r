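# Deformation maps phi(X, t): positional correspondence from the initial
# configuration to stage t. Two concrete kinds share one interface:
#   * fitted_map    -- a chain of per-interval regression fits
#   * synthetic_map -- ground truth built from a closed-form xi-space flow,
#                      an average-growth schedule L(tau) and a stage warp
# plus conjugate_map (rescaled/warped view of another map, used to build a
# second species sharing a flow) and rebased_map (same dynamics re-referenced
# to a later initial stage).

#' Evaluate a deformation map
#'
#' @param map A deformation map (`fitted_map`, `synthetic_map`, ...).
#' @param X n x 2 matrix of initial positions (micrometres).
#' @param t Stage at which to evaluate.
#' @return n x 2 matrix of deformed positions.
#' @export
evaluate_map <- function(map, X, t) UseMethod("evaluate_map")

#' Positions along the trajectory of material points
#'
#' @inheritParams evaluate_map
#' @param stages Increasing vector of stages within the map's range.
#' @return Array `n x 2 x length(stages)`.
#' @export
map_trajectory <- function(map, X, stages) UseMethod("map_trajectory")

#' Deformation gradient tensor F = d phi / d X
#'
#' @inheritParams evaluate_map
#' @return Array `2 x 2 x n`.
#' @export
deformation_gradient <- function(map, X, t) UseMethod("deformation_gradient")

gradient_trajectory <- function(map, X, stages) UseMethod("gradient_trajectory")

#' Stage range covered by a map
#' @param map A deformation map.
#' @return Length-2 numeric `c(first stage, last stage)`.
#' @export
map_stage_range <- function(map) UseMethod("map_stage_range")

#' Initial tissue outline attached to a map
#' @param map A deformation map.
#' @return A [tissue_outline()] or `NULL`.
#' @export
initial_outline <- function(map) UseMethod("initial_outline")

#' @export
initial_outline.default <- function(map) map$outline

as_points <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) != 2L) X <- matrix(as.numeric(X), ncol = 2L)
  storage.mode(X) <- "double"
  X
}

check_stage <- function(map, t) {
  rng <- map_stage_range(map)
  tol <- 1e-8 * max(1, diff(rng))
  if (any(t < rng[1L] - tol) || any(t > rng[2L] + tol)) {
    abort(sprintf("stage %.4g outside the map's range [%.4g, %.4g]",
                  t[which(t < rng[1L] - tol | t > rng[2L] + tol)][1L], rng[1L], rng[2L]),
          class = "morphodyn_domain_error")
  }
  pmin(pmax(t, rng[1L]), rng[2L])
}

## ---- fitted maps -----------------------------------------------------------

#' Compose per-interval fits into a full deformation map
#'
#' Chains interval maps so that the configuration at the end of interval k is
#' the input of interval k+1; stages inside an interval are reached by linear
#' interpolation of the displacement.
#'
#' @param maps List of [fit_interval_map()] results with contiguous stage
#'   intervals.
#' @param outline Optional [tissue_outline()] of the initial configuration
#'   (used for inversion seeding and decomposition).
#' @return Object of class `fitted_map` (also `deformation_map`).
#' @export
compose_maps <- function(maps, outline = NULL) {
  if (length(maps) < 1L) abort("need at least one interval map", class = "morphodyn_value_error")
  starts <- vapply(maps, function(m) m$stage_start, numeric(1L))
  ends <- vapply(maps, function(m) m$stage_end, numeric(1L))
  ord <- order(starts)
  maps <- maps[ord]; starts <- starts[ord]; ends <- ends[ord]
  if (any(!is.finite(starts)) || any(!is.finite(ends))) {
    abort("interval maps must carry stage_start/stage_end", class = "morphodyn_value_error")
  }
  tol <- 1e-8 * max(1, diff(range(c(starts, ends))))
  if (length(maps) > 1L && any(abs(starts[-1L] - ends[-length(ends)]) > tol)) {
    abort("intervals have a gap or overlap: cannot compose", class = "morphodyn_composition_error")
  }
  structure(list(interval_maps = maps, stages = c(starts, ends[length(ends)]),
                 outline = outline),
            class = c("fitted_map", "deformation_map"))
}

#' @export
map_stage_range.fitted_map <- function(map) range(map$stages)

fm_boundary_configs <- function(map, X, k_max) {
  out <- vector("list", k_max + 1L)
  out[[1L]] <- X
  for (j in seq_len(k_max)) out[[j + 1L]] <- im_eval(map$interval_maps[[j]], out[[j]])
  out
}

#' @export
map_trajectory.fitted_map <- function(map, X, stages) {
  X <- as_points(X)
  stages <- check_stage(map, stages)
  bounds <- map$stages
  K <- length(map$interval_maps)
  kf <- pmin(findInterval(stages, bounds), K)   # interval index containing t
  cfg <- fm_boundary_configs(map, X, max(kf))
  out <- array(NA_real_, dim = c(nrow(X), 2L, length(stages)))
  for (i in seq_along(stages)) {
    k <- kf[i]
    s <- (stages[i] - bounds[k]) / (bounds[k + 1L] - bounds[k])
    out[, , i] <- cfg[[k]] + s * (cfg[[k + 1L]] - cfg[[k]])
  }
  out
}

#' @export
evaluate_map.fitted_map <- function(map, X, t) {
  slice3(map_trajectory(map, X, t), 1L)
}

#' @export
gradient_trajectory.fitted_map <- function(map, X, stages) {
  X <- as_points(X)
  stages <- check_stage(map, stages)
  bounds <- map$stages
  K <- length(map$interval_maps)
  kf <- pmin(findInterval(stages, bounds), K)
  kmax <- max(kf)
  cfg <- fm_boundary_configs(map, X, kmax)
  n <- nrow(X)
  # accumulated Jacobians at interval boundaries
  Jb <- vector("list", kmax + 1L)
  Jb[[1L]] <- array(rep(diag(2), n), dim = c(2L, 2L, n))
  for (j in seq_len(kmax)) {
    Jj <- im_jac(map$interval_maps[[j]], cfg[[j]])
    Jb[[j + 1L]] <- mat_chain(Jj, Jb[[j]])
  }
  out <- array(NA_real_, dim = c(2L, 2L, n, length(stages)))
  for (i in seq_along(stages)) {
    k <- kf[i]
    s <- (stages[i] - bounds[k]) / (bounds[k + 1L] - bounds[k])
    if (s <= 0) {
      out[, , , i] <- Jb[[k]]
    } else if (s >= 1) {
      out[, , , i] <- Jb[[k + 1L]]
    } else {
      Jk1 <- im_jac(map$interval_maps[[k]], cfg[[k]])
      blend <- (1 - s) * array(rep(diag(2), n), dim = c(2L, 2L, n)) + s * Jk1
      out[, , , i] <- mat_chain(blend, Jb[[k]])
    }
  }
  out
}

#' @export
deformation_gradient.fitted_map <- function(map, X, t) {
  slice4(gradient_trajectory(map, X, t), 1L)
}

#' @export
initial_outline.fitted_map <- function(map) map$outline

# elementwise 2x2 matrix product over the third index: A[, , i] %*% B[, , i]
mat_chain <- function(A, B) {
  out <- array(NA_real_, dim = dim(B))
  out[1L, 1L, ] <- A[1L, 1L, ] * B[1L, 1L, ] + A[1L, 2L, ] * B[2L, 1L, ]
  out[2L, 1L, ] <- A[2L, 1L, ] * B[1L, 1L, ] + A[2L, 2L, ] * B[2L, 1L, ]
  out[1L, 2L, ] <- A[1L, 1L, ] * B[1L, 2L, ] + A[1L, 2L, ] * B[2L, 2L, ]
  out[2L, 2L, ] <- A[2L, 1L, ] * B[1L, 2L, ] + A[2L, 2L, ] * B[2L, 2L, ]
  out
}

## ---- synthetic maps --------------------------------------------------------

# RK4 integration of xi trajectories d xi/d tau = v(xi, tau), optionally with
# the variational equation dJ/dtau = (dv/dxi) J for exact spatial Jacobians.
rk4_flow <- function(flow, xi0, tau0, targets, h_base, with_jac = FALSE) {
  n <- nrow(xi0)
  xi <- xi0
  J <- if (with_jac) matrix(rep(c(1, 0, 0, 1), each = n), n, 4L) else NULL
  S <- length(targets)
  xi_out <- array(NA_real_, dim = c(n, 2L, S))
  J_out <- if (with_jac) array(NA_real_, dim = c(n, 4L, S)) else NULL
  deriv <- function(xi, J, tau) {
    v <- flow$v(xi, tau)
    dJ <- NULL
    if (with_jac) {
      a <- flow$dv(xi, tau)  # n x 4: (dv1/dx1, dv2/dx1, dv1/dx2, dv2/dx2)
      dJ <- cbind(a[, 1L] * J[, 1L] + a[, 3L] * J[, 2L],
                  a[, 2L] * J[, 1L] + a[, 4L] * J[, 2L],
                  a[, 1L] * J[, 3L] + a[, 3L] * J[, 4L],
                  a[, 2L] * J[, 3L] + a[, 4L] * J[, 4L])
    }
    list(v = v, dJ = dJ)
  }
  tau <- tau0
  for (s in seq_len(S)) {
    span <- targets[s] - tau
    if (span > 1e-14) {
      nstep <- max(1L, ceiling(span / h_base))
      h <- span / nstep
      for (step in seq_len(nstep)) {
        k1 <- deriv(xi, J, tau)
        k2 <- deriv(xi + h / 2 * k1$v, if (with_jac) J + h / 2 * k1$dJ else NULL, tau + h / 2)
        k3 <- deriv(xi + h / 2 * k2$v, if (with_jac) J + h / 2 * k2$dJ else NULL, tau + h / 2)
        k4 <- deriv(xi + h * k3$v, if (with_jac) J + h * k3$dJ else NULL, tau + h)
        xi <- xi + h / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
        if (with_jac) J <- J + h / 6 * (k1$dJ + 2 * k2$dJ + 2 * k3$dJ + k4$dJ)
        tau <- tau + h
      }
    }
    xi_out[, , s] <- xi
    if (with_jac) J_out[, , s] <- J
  }
  list(xi = xi_out, J = J_out)
}

synth_tau <- function(map, t) (t - map$warp[2L]) / map$warp[1L]

#' @export
map_stage_range.synthetic_map <- function(map) {
  sort(map$warp[1L] * map$tau_span + map$warp[2L])
}

synth_step <- function(map) diff(map$tau_span) / map$n_steps

#' @export
map_trajectory.synthetic_map <- function(map, X, stages) {
  X <- as_points(X)
  stages <- check_stage(map, stages)
  ord <- order(stages)
  taus <- synth_tau(map, stages[ord])
  res <- rk4_flow(map$flow, X / map$C0, map$tau_span[1L], taus, synth_step(map))
  out <- array(NA_real_, dim = c(nrow(X), 2L, length(stages)))
  for (i in seq_along(taus)) {
    L <- map$L_fn(taus[i])
    out[, , ord[i]] <- res$xi[, , i] %*% t(L) +
      matrix(map$xbar_fn(taus[i]), nrow(X), 2L, byrow = TRUE)
  }
  out
}

#' @export
evaluate_map.synthetic_map <- function(map, X, t) slice3(map_trajectory(map, X, t), 1L)

#' @export
gradient_trajectory.synthetic_map <- function(map, X, stages) {
  X <- as_points(X)
  stages <- check_stage(map, stages)
  ord <- order(stages)
  taus <- synth_tau(map, stages[ord])
  res <- rk4_flow(map$flow, X / map$C0, map$tau_span[1L], taus, synth_step(map),
                  with_jac = TRUE)
  n <- nrow(X)
  out <- array(NA_real_, dim = c(2L, 2L, n, length(stages)))
  for (i in seq_along(taus)) {
    L <- map$L_fn(taus[i])
    J <- res$J[, , i, drop = FALSE][, , 1L]  # n x 4 (J11, J21, J12, J22)
    if (is.null(dim(J))) J <- matrix(J, n, 4L)
    # F = L %*% Jxi / C0
    F11 <- (L[1L, 1L] * J[, 1L] + L[1L, 2L] * J[, 2L]) / map$C0
    F21 <- (L[2L, 1L] * J[, 1L] + L[2L, 2L] * J[, 2L]) / map$C0
    F12 <- (L[1L, 1L] * J[, 3L] + L[1L, 2L] * J[, 4L]) / map$C0
    F22 <- (L[2L, 1L] * J[, 3L] + L[2L, 2L] * J[, 4L]) / map$C0
    out[1L, 1L, , ord[i]] <- F11; out[2L, 1L, , ord[i]] <- F21
    out[1L, 2L, , ord[i]] <- F12; out[2L, 2L, , ord[i]] <- F22
  }
  out
}

#' @export
deformation_gradient.synthetic_map <- function(map, X, t) {
  slice4(gradient_trajectory(map, X, t), 1L)
}

## ---- conjugated maps -------------------------------------------------------

#' Rescaled, rotated, stage-warped view of another deformation map
#'
#' Builds the conjugated map `phi'(X, t) = s Q phi(Q' X / s, (t - b) / a)`
#' with Q the rotation by `rotation`. Because a similarity transformation
#' commutes with the growth/rescaling decomposition, the conjugate's rescaled
#' dynamics coincide with the parent's: the construction used to plant a
#' second species that shares a flow exactly.
#'
#' @param parent A deformation map.
#' @param scale Similarity scale factor s.
#' @param warp Stage warp `c(a, b)`: child stage t = a * t_parent + b.
#' @param rotation Rotation angle (radians).
#' @param outline Initial [tissue_outline()] of the conjugate.
#' @return Object of class `conjugate_map` (also `deformation_map`).
#' @export
conjugate_map <- function(parent, scale = 1, warp = c(1, 0), rotation = 0,
                          outline = NULL) {
  structure(list(parent = parent, scale = scale, warp = warp,
                 Q = rot2(rotation), outline = outline),
            class = c("conjugate_map", "deformation_map"))
}

#' @export
map_stage_range.conjugate_map <- function(map) {
  sort(map$warp[1L] * map_stage_range(map$parent) + map$warp[2L])
}

#' @export
map_trajectory.conjugate_map <- function(map, X, stages) {
  stages <- check_stage(map, stages)
  tp <- (stages - map$warp[2L]) / map$warp[1L]
  Xp <- (as_points(X) %*% map$Q) / map$scale      # Q^T X / s (row vectors)
  out <- map_trajectory(map$parent, Xp, tp)
  for (s in seq_along(tp)) out[, , s] <- map$scale * (slice3(out, s) %*% t(map$Q))
  out
}

#' @export
evaluate_map.conjugate_map <- function(map, X, t) slice3(map_trajectory(map, X, t), 1L)

#' @export
gradient_trajectory.conjugate_map <- function(map, X, stages) {
  stages <- check_stage(map, stages)
  tp <- (stages - map$warp[2L]) / map$warp[1L]
  Xp <- (as_points(X) %*% map$Q) / map$scale
  G <- gradient_trajectory(map$parent, Xp, tp)
  n <- dim(G)[3L]
  Qa <- array(rep(map$Q, n), dim = c(2L, 2L, n))
  Qta <- array(rep(t(map$Q), n), dim = c(2L, 2L, n))
  for (s in seq_along(tp)) G[, , , s] <- mat_chain(mat_chain(Qa, G[, , , s]), Qta)
  G
}

#' @export
deformation_gradient.conjugate_map <- function(map, X, t) {
  slice4(gradient_trajectory(map, X, t), 1L)
}

## ---- rebased maps ----------------------------------------------------------

# The same dynamics, re-referenced so that the configuration at stage t0
# becomes the initial configuration: phi'(X', t) = phi(phi^{-1}(X', t0), t).
rebase_map <- function(map, t0, outline = NULL) {
  t0 <- check_stage(map, t0)
  if (is.null(outline)) {
    base <- initial_outline(map)
    if (!is.null(base)) {
      ring <- resample_ring(outline_ring(base), 128L)
      outline <- tissue_outline(evaluate_map(map, ring, t0), stage = t0)
    }
  }
  structure(list(parent = map, t0 = t0, outline = outline),
            class = c("rebased_map", "deformation_map"))
}

#' @export
map_stage_range.rebased_map <- function(map) c(map$t0, map_stage_range(map$parent)[2L])

#' @export
map_trajectory.rebased_map <- function(map, X, stages) {
  stages <- check_stage(map, stages)
  X0 <- invert_map(map$parent, as_points(X), map$t0)
  map_trajectory(map$parent, X0, stages)
}

#' @export
evaluate_map.rebased_map <- function(map, X, t) slice3(map_trajectory(map, X, t), 1L)

#' @export
gradient_trajectory.rebased_map <- function(map, X, stages) {
  stages <- check_stage(map, stages)
  X0 <- invert_map(map$parent, as_points(X), map$t0)
  G0 <- deformation_gradient(map$parent, X0, map$t0)
  Gt <- gradient_trajectory(map$parent, X0, stages)
  inv0 <- G0
  for (i in seq_len(dim(G0)[3L])) inv0[, , i] <- solve(G0[, , i])
  out <- Gt
  for (s in seq_len(dim(Gt)[4L])) out[, , , s] <- mat_chain(Gt[, , , s], inv0)
  out
}

#' @export
deformation_gradient.rebased_map <- function(map, X, t) {
  slice4(gradient_trajectory(map, X, t), 1L)
}

#' Pointwise reconstruction uncertainty of a fitted map
#'
#' Propagates each interval fit's Gaussian-process posterior predictive
#' variance through the composition chain (transported by the downstream
#' Jacobians), giving the pointwise standard deviation of the reconstructed
#' position. Together with bootstrap resampling spread this quantifies the
#' total pointwise spread of the reconstruction.
#'
#' @param map A `fitted_map`.
#' @param X n x 2 initial positions.
#' @param t Stage.
#' @return n x 2 matrix of per-component standard deviations (micrometres).
#' @export
map_pointwise_sd <- function(map, X, t) {
  stopifnot(inherits(map, "fitted_map"))
  X <- as_points(X)
  t <- check_stage(map, t)
  bounds <- map$stages
  K <- length(map$interval_maps)
  k_t <- min(findInterval(t, bounds), K)
  s_frac <- (t - bounds[k_t]) / (bounds[k_t + 1L] - bounds[k_t])
  n <- nrow(X)
  Y <- X
  V <- array(0, dim = c(2L, 2L, n))
  for (k in seq_len(if (s_frac > 0) k_t else k_t - 1L)) {
    im <- map$interval_maps[[k]]
    J <- im_jac(im, Y)
    V <- mat_chain(mat_chain(J, V), aperm(J, c(2L, 1L, 3L)))
    w <- if (k == k_t && s_frac > 0 && s_frac < 1) s_frac^2 else 1
    pv <- w * im_post_var(im, Y)
    V[1L, 1L, ] <- V[1L, 1L, ] + pv
    V[2L, 2L, ] <- V[2L, 2L, ] + pv
    Y <- if (k == k_t && s_frac > 0 && s_frac < 1) Y + s_frac * (im_eval(im, Y) - Y)
         else im_eval(im, Y)
  }
  cbind(sqrt(pmax(V[1L, 1L, ], 0)), sqrt(pmax(V[2L, 2L, ], 0)))
}

## ---- inversion and advection ----------------------------------------------

#' Invert a deformation map
#'
#' Finds the initial positions X with phi(X, t) = x by Newton iteration,
#' initialized from the nearest node of a coarse evaluation grid over the
#' initial domain.
#'
#' @param map A deformation map.
#' @param x n x 2 matrix of deformed positions at stage `t`.
#' @param t Stage.
#' @param tol Convergence tolerance on `|phi(X, t) - x|` in micrometres.
#' @param max_iter Maximum Newton iterations.
#' @return n x 2 matrix of initial positions.
#' @export
invert_map <- function(map, x, t, tol = 1e-6, max_iter = 60L) UseMethod("invert_map")

#' @export
invert_map.synthetic_map <- function(map, x, t, tol = 1e-6, max_iter = 60L) {
  x <- as_points(x)
  t <- check_stage(map, t)
  tau <- synth_tau(map, t)
  L <- map$L_fn(tau)
  xi_t <- (x - matrix(map$xbar_fn(tau), nrow(x), 2L, byrow = TRUE)) %*% t(solve(L))
  # integrate the flow backwards to tau0
  back <- list(v = function(xi, s) -map$flow$v(xi, tau - (s - map$tau_span[1L])),
               dv = map$flow$dv)
  span <- tau - map$tau_span[1L]
  if (span <= 1e-14) return(xi_t * map$C0)
  res <- rk4_flow(back, xi_t, map$tau_span[1L], map$tau_span[1L] + span, synth_step(map))
  res$xi[, , 1L] * map$C0
}

#' @export
invert_map.default <- function(map, x, t, tol = 1e-6, max_iter = 60L) {
  x <- as_points(x)
  t <- check_stage(map, t)
  dom <- initial_outline(map)
  if (!is.null(dom)) {
    ring <- outline_ring(dom)
    rx <- range(ring[, 1L]); ry <- range(ring[, 2L])
  } else if (inherits(map, "fitted_map")) {
    Xtr <- map$interval_maps[[1L]]$Xtrain
    rx <- range(Xtr[, 1L]); ry <- range(Xtr[, 2L])
  } else {
    abort("no initial domain available for inversion seeding", class = "morphodyn_value_error")
  }
  g <- as.matrix(expand.grid(seq(rx[1L], rx[2L], length.out = 9L),
                             seq(ry[1L], ry[2L], length.out = 9L)))
  gx <- evaluate_map(map, g, t)
  X <- g[apply(x, 1L, function(p) which.min((gx[, 1L] - p[1L])^2 + (gx[, 2L] - p[2L])^2)), ,
         drop = FALSE]
  resid <- rep(Inf, nrow(x))
  for (iter in seq_len(max_iter)) {
    fx <- evaluate_map(map, X, t)
    err <- x - fx
    resid <- sqrt(rowSums(err^2))
    active <- resid > tol
    if (!any(active)) break
    Fa <- deformation_gradient(map, X[active, , drop = FALSE], t)
    for (j in seq_len(sum(active))) {
      i <- which(active)[j]
      step <- tryCatch(solve(Fa[, , j], err[i, ]), error = function(e) c(0, 0))
      X[i, ] <- X[i, ] + step
    }
  }
  if (any(resid > tol)) {
    abort(sprintf("map inversion did not converge: best residual %.3g um", max(resid)),
          class = "morphodyn_inversion_error")
  }
  X
}

#' Advect points from one stage to another along the map
#'
#' @param map A deformation map.
#' @param p n x 2 matrix of positions at stage `t_from`.
#' @param t_from,t_to Stages in the map's range.
#' @return n x 2 matrix of positions at `t_to`.
#' @export
advect_points <- function(map, p, t_from, t_to) {
  X <- invert_map(map, as_points(p), t_from)
  evaluate_map(map, X, t_to)
}

## ---- local deformation summary --------------------------------------------

#' Local deformation summary of a gradient tensor
#'
#' Decomposes F into the local area growth ratio (det F), the deformation
#' anisotropy magnitude log(lambda1 / lambda2) of the principal stretches of
#' the right stretch tensor U = (F'F)^(1/2), and the orientation of the major
#' stretch axis pushed forward into the deformed configuration (reported
#' modulo pi).
#'
#' @param F A 2 x 2 matrix or a 2 x 2 x n array of deformation gradients.
#' @return A tibble with columns `area_ratio`, `anisotropy`, `orientation`
#'   (radians in (-pi/2, pi/2]), and `orientation_defined` (`FALSE` where the
#'   deformation is isotropic and the axis is arbitrary).
#' @export
local_deformation_summary <- function(F) {
  if (length(dim(F)) == 2L) F <- array(F, dim = c(2L, 2L, 1L))
  n <- dim(F)[3L]
  out <- tibble::tibble(area_ratio = numeric(n), anisotropy = numeric(n),
                        orientation = numeric(n), orientation_defined = logical(n))
  for (i in seq_len(n)) {
    Fi <- F[, , i]
    detF <- Fi[1L, 1L] * Fi[2L, 2L] - Fi[1L, 2L] * Fi[2L, 1L]
    if (!is.finite(detF) || detF <= 0) {
      abort("deformation gradient must have positive determinant",
            class = "morphodyn_tensor_error")
    }
    sv <- svd(Fi)
    lam <- sv$d
    aniso <- log(lam[1L] / lam[2L])
    pushed <- sv$u[, 1L]     # direction of the major principal axis after deformation
    ang <- atan2(pushed[2L], pushed[1L]) %% pi
    if (ang > pi / 2) ang <- ang - pi
    defined <- aniso > 1e-8
    out$area_ratio[i] <- detF
    out$anisotropy[i] <- aniso
    out$orientation[i] <- if (defined) ang else NA_real_
    out$orientation_defined[i] <- defined
  }
  out
}

## ---- bootstrap -------------------------------------------------------------

#' Bootstrap the map reconstruction
#'
#' Resamples each interval's landmark pairs with replacement at the original
#' size, refits every interval, and composes each replicate into a full map.
#' Replicates whose resampled configuration is degenerate (collinear start
#' positions) are skipped and counted.
#'
#' @param data An `interval_data` tibble (see [build_interval_datasets()]).
#' @param B Number of bootstrap replicates (default 150).
#' @param seed Integer seed; replicate resampling is reproducible given it.
#' @param prior Passed to [fit_interval_map()].
#' @param reoptimize If `FALSE` (default), GP hyperparameters are taken from a
#'   reference fit on the original data and held fixed across replicates; set
#'   `TRUE` to re-run marginal-likelihood maximization per replicate.
#' @param outline Optional initial outline attached to every replicate map.
#' @return List of `fitted_map` replicates, with attribute `n_skipped`.
#' @export
bootstrap_maps <- function(data, B = 150L, seed = 1L, prior = NULL,
                           reoptimize = FALSE, outline = NULL) {
  if (B < 1L) abort("B must be >= 1", class = "morphodyn_value_error")
  ks <- sort(unique(data$interval))
  ref <- lapply(ks, function(k) {
    d <- data[data$interval == k, , drop = FALSE]
    suppressWarnings(fit_interval_map(d, prior = prior, check_fold = FALSE))
  })
  set.seed(seed)
  out <- vector("list", B)
  skipped <- 0L
  for (b in seq_len(B)) {
    maps <- vector("list", length(ks))
    ok <- TRUE
    for (j in seq_along(ks)) {
      d <- data[data$interval == ks[j], , drop = FALSE]
      idx <- sample.int(nrow(d), nrow(d), replace = TRUE)
      pr <- prior
      if (!reoptimize && ref[[j]]$use_gp) {
        pr <- utils::modifyList(prior %||% list(),
                                list(lengthscale = ref[[j]]$hyp$ell,
                                     signal_var = ref[[j]]$hyp$sf2,
                                     noise_var = ref[[j]]$hyp$sn2))
      }
      m <- tryCatch(
        suppressWarnings(fit_interval_map(d[idx, , drop = FALSE], prior = pr,
                                          check_fold = FALSE)),
        morphodyn_rank_error = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      maps[[j]] <- m
    }
    if (ok) out[[b]] <- compose_maps(maps, outline = outline) else skipped <- skipped + 1L
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (skipped > 0L) {
    warn(sprintf("%d bootstrap replicate(s) skipped (degenerate resample)", skipped),
         class = "morphodyn_bootstrap_skip")
  }
  attr(out, "n_skipped") <- skipped
  out
}
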