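# Decomposition of a deformation map into average growth and rescaled
# (xi-space) dynamics:
#   xi(xi0, t) = L^{-1}(t) (x(X, t) - xbar(t)),   L(t) = C0 * Fbar(t)
# with xi0 = X / C0. All decomposition output uses a frame in which the
# initial area centroid is at the origin and the material point initially at
# the origin stays at the origin (its tracked position is subtracted).

#' Centroid size of a tissue outline
#'
#' Root-mean-square distance of boundary samples from their centroid,
#' computed over `M` equally arc-length-spaced samples of the outline ring
#' so the value is independent of vertex density.
#'
#' @param outline A [tissue_outline()] or vertex ring.
#' @param M Number of boundary samples (default 200).
#' @return Centroid size in micrometres.
#' @export
centroid_size <- function(outline, M = 200L) {
  ring <- outline_ring(outline)
  if (poly_area(ring) <= 0) abort("degenerate outline", class = "morphodyn_geometry_error")
  p <- resample_ring(ring, M)
  ctr <- colMeans(p)
  sqrt(sum((p[, 1L] - ctr[1L])^2 + (p[, 2L] - ctr[2L])^2) / M)
}

#' Spatial average of the deformation gradient over the initial domain
#'
#' Area-weighted quadrature of F(X, t) over the initial outline: the grid of
#' cell centres over the bounding box is clipped to the polygon, so the
#' average converges with grid refinement.
#'
#' @param map A deformation map.
#' @param t Stage.
#' @param outline Initial [tissue_outline()]; defaults to the map's own.
#' @param n_grid Quadrature grid resolution per axis (default 25).
#' @return 2 x 2 matrix Fbar(t).
#' @export
mean_deformation_gradient <- function(map, t, outline = NULL, n_grid = 25L) {
  outline <- outline %||% initial_outline(map)
  if (is.null(outline)) abort("an initial outline is required", class = "morphodyn_value_error")
  qp <- quad_points(outline_ring(outline), n_grid)
  Fq <- deformation_gradient(map, qp$points, t)
  w <- qp$weights / sum(qp$weights)
  matrix(matrix(Fq, nrow = 4L) %*% w, 2L, 2L)
}

#' Decompose a deformation map into average growth and rescaled dynamics
#'
#' Computes the initial centroid size C0, the mean deformation gradient
#' trajectory Fbar(t) and with it the multi-dimensional tissue size
#' L(t) = C0 Fbar(t), the deformed-domain centroid path xbar(t) (initial area
#' elements weighted by det F), and the rescaled trajectories
#' xi(xi0, t) = L^{-1}(t)(x - xbar) on a regular seed lattice in xi0 clipped
#' to the initial outline. Recombining L * xi + xbar reproduces the map
#' identically by construction.
#'
#' @param map A deformation map.
#' @param outline Initial [tissue_outline()]; defaults to the map's own.
#' @param stages Stage grid for the decomposition; default 21 evenly spaced
#'   stages over the map's range.
#' @param n_quad Quadrature resolution per axis for the area averages.
#' @param seed_spacing Seed lattice spacing in dimensionless xi0 units
#'   (default 0.02).
#' @param species Optional species label carried through to results.
#' @return A list of class `tissue_decomposition` with elements `growth`
#'   (class `mean_growth`) and `xi` (class `xi_dynamics`).
#' @export
decompose <- function(map, outline = NULL, stages = NULL, n_quad = 25L,
                      seed_spacing = 0.02, species = NULL) {
  outline <- outline %||% initial_outline(map)
  if (is.null(outline)) abort("an initial outline is required", class = "morphodyn_value_error")
  ring <- outline_ring(outline)
  rng <- map_stage_range(map)
  stages <- stages %||% seq(rng[1L], rng[2L], length.out = 21L)
  stages <- sort(unique(as.numeric(stages)))
  S <- length(stages)

  qp <- quad_points(ring, n_quad)
  wq <- qp$weights / sum(qp$weights)
  c0 <- poly_centroid(ring)
  Xq <- sweep(qp$points, 2L, c0)
  ring_c <- sweep(ring, 2L, c0)
  C0 <- centroid_size(ring_c)

  phi0 <- t(map_trajectory(map, matrix(c0, 1L, 2L), stages)[1L, , ])  # S x 2
  if (S == 1L) phi0 <- matrix(phi0, 1L, 2L)
  pos <- map_trajectory(map, qp$points, stages)                       # n x 2 x S
  Fq <- gradient_trajectory(map, qp$points, stages)                   # 2 x 2 x n x S
  # centroid path: area centroid of the advected outline (robust to local
  # Jacobian error, and zero at the initial stage by construction)
  bnd <- sweep(resample_ring(ring_c, 200L), 2L, c0, "+")
  bnd_traj <- map_trajectory(map, bnd, stages)

  Fbar <- array(NA_real_, dim = c(2L, 2L, S))
  L <- array(NA_real_, dim = c(2L, 2L, S))
  Linv <- array(NA_real_, dim = c(2L, 2L, S))
  xbar <- matrix(NA_real_, S, 2L)
  for (s in seq_len(S)) {
    Fs <- Fq[, , , s]
    Fbar[, , s] <- matrix(matrix(Fs, nrow = 4L) %*% wq, 2L, 2L)
    detF <- Fs[1L, 1L, ] * Fs[2L, 2L, ] - Fs[1L, 2L, ] * Fs[2L, 1L, ]
    if (any(detF <= 0)) {
      warn(sprintf("non-positive det F at %d quadrature point(s), stage %.4g",
                   sum(detF <= 0), stages[s]),
           class = "morphodyn_fold_warning")
      detF <- pmax(detF, 1e-12)
    }
    xbar[s, ] <- poly_centroid(sweep(slice3(bnd_traj, s), 2L, phi0[s, ]))
    L[, , s] <- C0 * Fbar[, , s]
    d <- L[1L, 1L, s] * L[2L, 2L, s] - L[1L, 2L, s] * L[2L, 1L, s]
    if (abs(d) < .Machine$double.eps) {
      abort(sprintf("singular average growth tensor at stage %.4g", stages[s]),
            class = "morphodyn_decomposition_error")
    }
    Linv[, , s] <- solve(L[, , s])
  }

  # Sbar(t) from d Fbar / dt = Sbar Fbar, by central differences on the grid
  Sbar <- array(NA_real_, dim = c(2L, 2L, S))
  for (s in seq_len(S)) {
    lo <- max(1L, s - 1L); hi <- min(S, s + 1L)
    dF <- (Fbar[, , hi] - Fbar[, , lo]) / (stages[hi] - stages[lo])
    Sbar[, , s] <- dF %*% solve(Fbar[, , s])
  }

  growth <- structure(list(
    C0 = C0, stages = stages, Fbar = Fbar, L = L, Linv = Linv,
    xbar = xbar, Sbar = Sbar, center = c0, phi0 = phi0,
    outline = ring_c, map = map, species = species
  ), class = "mean_growth")

  seeds_tb <- lattice_in_polygon(ring_c / C0, seed_spacing)
  xi0 <- cbind(seeds_tb$x, seeds_tb$y)
  traj <- xi_trajectories(growth, xi0, stages)

  xi <- structure(list(
    seeds = tibble::tibble(seed = seq_len(nrow(xi0)), ix = seeds_tb$ix, iy = seeds_tb$iy,
                           xi0_pd = xi0[, 1L], xi0_ap = xi0[, 2L]),
    xi0 = xi0, traj = traj, stages = stages, spacing = seed_spacing,
    outline_xi = ring_c / C0, growth = growth, species = species
  ), class = "xi_dynamics")

  structure(list(growth = growth, xi = xi), class = "tissue_decomposition")
}

#' @export
print.tissue_decomposition <- function(x, ...) {
  cat("<tissue_decomposition> C0 = ", signif(x$growth$C0, 4), " um, ",
      length(x$growth$stages), " stages, ", nrow(x$xi$xi0), " xi seeds\n", sep = "")
  invisible(x)
}

# interpolate stored per-stage quantities at an arbitrary stage
interp_stage <- function(stages, values_fn, t) {
  S <- length(stages)
  if (t <= stages[1L]) return(values_fn(1L))
  if (t >= stages[S]) return(values_fn(S))
  k <- findInterval(t, stages)
  w <- (t - stages[k]) / (stages[k + 1L] - stages[k])
  (1 - w) * values_fn(k) + w * values_fn(k + 1L)
}

growth_L <- function(growth, t) interp_stage(growth$stages, function(s) growth$L[, , s], t)
growth_xbar <- function(growth, t) interp_stage(growth$stages, function(s) growth$xbar[s, ], t)
growth_Sbar <- function(growth, t) interp_stage(growth$stages, function(s) growth$Sbar[, , s], t)

# phi in the decomposition frame (initial centroid at origin, material origin
# pinned): phi_hat(X, t) = phi(X + c0, t) - phi(c0, t)
phi_hat_traj <- function(growth, X, stages) {
  pos <- map_trajectory(growth$map, sweep(as_points(X), 2L, growth$center, "+"), stages)
  p0 <- map_trajectory(growth$map, matrix(growth$center, 1L, 2L), stages)
  for (s in seq_along(stages)) pos[, , s] <- sweep(slice3(pos, s), 2L, p0[1L, , s])
  pos
}

# xi trajectories for arbitrary seeds at the decomposition's grid stages
xi_trajectories <- function(growth, xi0, stages = growth$stages) {
  X <- as_points(xi0) * growth$C0
  pos <- phi_hat_traj(growth, X, stages)
  out <- array(NA_real_, dim = dim(pos))
  grid_idx <- match(round(stages, 10L), round(growth$stages, 10L))
  for (s in seq_along(stages)) {
    Li <- if (!is.na(grid_idx[s])) growth$Linv[, , grid_idx[s]] else
      solve(growth_L(growth, stages[s]))
    out[, , s] <- sweep(pos[, , s], 2L, growth_xbar(growth, stages[s])) %*% t(Li)
  }
  out
}

#' Rescaled positions of trajectory seeds at given stages
#'
#' @param dyn A `xi_dynamics` object from [decompose()].
#' @param xi0 n x 2 matrix of dimensionless initial positions; defaults to
#'   the stored seed lattice.
#' @param stages Stages at which to evaluate; default the decomposition grid.
#' @return Array `n x 2 x length(stages)`.
#' @export
xi_at <- function(dyn, xi0 = NULL, stages = NULL) {
  stopifnot(inherits(dyn, "xi_dynamics"))
  if (is.null(xi0) && is.null(stages)) return(dyn$traj)
  xi0 <- if (is.null(xi0)) dyn$xi0 else as_points(xi0)
  stages <- stages %||% dyn$stages
  xi_trajectories(dyn$growth, xi0, stages)
}

# line-segment average of F: G(X, t) = int_0^1 F(eps X, t) d eps, in the
# decomposition frame. Returns 2 x 2 x n.
line_avg_gradient <- function(growth, X, t, n_eps = 16L, rule = c("gauss", "midpoint")) {
  rule <- match.arg(rule)
  X <- as_points(X)
  nodes <- if (rule == "gauss") {
    gl <- pracma::gaussLegendre(n_eps, 0, 1)
    list(e = gl$x, w = gl$w)
  } else {
    list(e = (seq_len(n_eps) - 0.5) / n_eps, w = rep(1 / n_eps, n_eps))
  }
  n <- nrow(X)
  G <- array(0, dim = c(2L, 2L, n))
  for (q in seq_along(nodes$e)) {
    pts <- sweep(X * nodes$e[q], 2L, growth$center, "+")
    Fq <- deformation_gradient(growth$map, pts, t)
    G <- G + nodes$w[q] * Fq
  }
  G
}

#' Velocity field of the rescaled dynamics
#'
#' Evaluates the xi-space velocity
#' \deqn{\partial\xi/\partial t = L^{-1}(\bar S_X - \bar S) L \xi - v_g}
#' where \eqn{\bar S} is the tissue-average velocity-gradient tensor
#' (from d Fbar/dt = Sbar Fbar), \eqn{\bar S_X} its line-segment-average
#' counterpart at the focal initial position, and
#' \eqn{v_g = L^{-1}(d\bar x/dt - \bar S_X \bar x)} the contribution of the
#' moving tissue centroid. Temporal derivatives are central differences on
#' the decomposition stage grid (one-sided at the grid ends, with a warning).
#'
#' @param dyn A `xi_dynamics` object.
#' @param xi0 Seeds (n x 2, dimensionless); default the stored lattice.
#' @param stages Stages (subset of the decomposition grid); default all.
#' @param include_vg Include the centroid term (default `TRUE`). `FALSE`
#'   reproduces the small-centroid-motion approximation.
#' @param n_eps Number of quadrature nodes for the line-segment average
#'   (default 32; the integrand is only piecewise smooth near the domain
#'   boundary, so generous quadrature matters for near-edge seeds).
#' @return Array `n x 2 x length(stages)` of dimensionless velocities per
#'   stage unit.
#' @export
xi_velocity <- function(dyn, xi0 = NULL, stages = NULL, include_vg = TRUE, n_eps = 32L) {
  stopifnot(inherits(dyn, "xi_dynamics"))
  growth <- dyn$growth
  grid <- growth$stages
  S <- length(grid)
  xi0 <- if (is.null(xi0)) dyn$xi0 else as_points(xi0)
  stages <- stages %||% grid
  idx <- match(round(stages, 10L), round(grid, 10L))
  if (anyNA(idx)) {
    abort("xi_velocity stages must lie on the decomposition stage grid",
          class = "morphodyn_value_error")
  }
  if (any(idx == 1L | idx == S)) {
    warn("one-sided time difference at the stage-grid boundary",
         class = "morphodyn_boundary_warning")
  }
  X <- xi0 * growth$C0
  n <- nrow(X)
  # xi and G at needed stages (neighbours included for differencing)
  need <- sort(unique(c(idx, pmax(idx - 1L, 1L), pmin(idx + 1L, S))))
  Gs <- lapply(need, function(s) line_avg_gradient(growth, X, grid[s], n_eps = n_eps))
  names(Gs) <- as.character(need)
  xis <- xi_trajectories(growth, xi0, grid[idx])

  out <- array(NA_real_, dim = c(n, 2L, length(stages)))
  for (j in seq_along(idx)) {
    s <- idx[j]
    lo <- max(1L, s - 1L); hi <- min(S, s + 1L)
    dt <- grid[hi] - grid[lo]
    G0 <- Gs[[as.character(s)]]
    Glo <- Gs[[as.character(lo)]]; Ghi <- Gs[[as.character(hi)]]
    Ls <- growth$L[, , s]; Lis <- growth$Linv[, , s]
    Sb <- growth$Sbar[, , s]
    dxbar <- (growth$xbar[hi, ] - growth$xbar[lo, ]) / dt
    xb <- growth$xbar[s, ]
    for (i in seq_len(n)) {
      SX <- ((Ghi[, , i] - Glo[, , i]) / dt) %*% solve(G0[, , i])
      vel <- Lis %*% (SX - Sb) %*% Ls %*% xis[i, , j]
      if (include_vg) vel <- vel - Lis %*% (dxbar - SX %*% xb)
      out[i, , j] <- vel
    }
  }
  out
}

#' Star-domain line-integral identity check
#'
#' For a smooth map on a domain star-shaped about the origin, the deformed
#' position satisfies \eqn{x(X,t) = (\int_0^1 F(\epsilon X, t) d\epsilon) X}
#' once the material origin is pinned (x(0, t) = 0). This function evaluates
#' the residual of that identity with the line integral approximated by
#' quadrature.
#'
#' @param map A deformation map.
#' @param X n x 2 initial positions, relative to the star centre.
#' @param t Stage.
#' @param n_eps Number of quadrature nodes (default 64).
#' @param rule `"gauss"` (Gauss-Legendre, default) or `"midpoint"`
#'   (second-order, useful for convergence studies).
#' @param center Star centre in the map's own coordinates; defaults to the
#'   area centroid of the initial outline.
#' @param recenter If `TRUE` (default) pin the material origin by subtracting
#'   phi(center, t); with `FALSE` the raw identity is tested and fails
#'   whenever the origin is not fixed.
#' @param outline Optional outline used to verify that the segments 0 -> X
#'   stay inside the domain.
#' @return Numeric vector of residuals |phi - G X| in micrometres.
#' @export
star_domain_identity_check <- function(map, X, t, n_eps = 64L,
                                       rule = c("gauss", "midpoint"),
                                       center = NULL, recenter = TRUE,
                                       outline = NULL) {
  rule <- match.arg(rule)
  X <- as_points(X)
  outline <- outline %||% initial_outline(map)
  if (is.null(center)) {
    center <- if (!is.null(outline)) poly_centroid(outline_ring(outline)) else c(0, 0)
  }
  if (!is.null(outline)) {
    ring_c <- sweep(outline_ring(outline), 2L, center)
    probe <- do.call(rbind, lapply(c(0.25, 0.5, 0.75, 1), function(e) X * e))
    if (!all(points_in_poly(probe, ring_c))) {
      abort("segment from the star centre to X leaves the domain",
            class = "morphodyn_star_error")
    }
  }
  nodes <- if (rule == "gauss") {
    gl <- pracma::gaussLegendre(n_eps, 0, 1)
    list(e = gl$x, w = gl$w)
  } else {
    list(e = (seq_len(n_eps) - 0.5) / n_eps, w = rep(1 / n_eps, n_eps))
  }
  n <- nrow(X)
  G <- array(0, dim = c(2L, 2L, n))
  for (q in seq_along(nodes$e)) {
    pts <- sweep(X * nodes$e[q], 2L, center, "+")
    G <- G + nodes$w[q] * deformation_gradient(map, pts, t)
  }
  phi <- evaluate_map(map, sweep(X, 2L, center, "+"), t)
  if (recenter) {
    phi <- sweep(phi, 2L, evaluate_map(map, matrix(center, 1L, 2L), t)[1L, ])
  }
  pred <- t(vapply(seq_len(n), function(i) as.numeric(G[, , i] %*% X[i, ]), numeric(2L)))
  sqrt(rowSums((phi - pred)^2))
}

#' Pseudo-map: one species' growth applied to the other's rescaled dynamics
#'
#' \deqn{\tilde\phi_A(X, \tau_1, \tau_2) = L_A(\tau_1) \xi_B(\xi_0, \tau_2) + \bar x_A(\tau_1)}
#' With A = B and tau1 = tau2 this reproduces the true map exactly; with the
#' clocks out of synchronization it exposes the mismatch of the flows.
#'
#' @param growth_a `mean_growth` of the species supplying average growth.
#' @param dyn_b `xi_dynamics` supplying rescaled positions.
#' @param xi0 Seeds (n x 2, dimensionless) shared by both species.
#' @param t_a Stage of species A at which growth is applied.
#' @param t_b Stage of species B at which the rescaled positions are taken.
#' @return Tibble with mapped positions `pd_um`, `ap_um` (species-A physical
#'   frame) and `valid` flagging seeds inside species B's initial domain.
#' @export
pseudo_map <- function(growth_a, dyn_b, xi0, t_a, t_b) {
  xi0 <- as_points(xi0)
  xib <- slice3(xi_at(dyn_b, xi0, t_b), 1L)
  if (is.null(dim(xib))) xib <- matrix(xib, ncol = 2L)
  La <- growth_L(growth_a, t_a)
  xb <- growth_xbar(growth_a, t_a)
  p0 <- evaluate_map(growth_a$map, matrix(growth_a$center, 1L, 2L), t_a)[1L, ]
  pos <- xib %*% t(La)
  pos <- sweep(pos, 2L, xb + p0, "+")
  valid <- points_in_poly(xi0, dyn_b$outline_xi)
  tibble::tibble(pd_um = pos[, 1L], ap_um = pos[, 2L], valid = valid)
}

#' Interspecies scaling operator
#'
#' The time-variant linear transformation carrying one species' average
#' growth onto the other's, `Lab = L_A %*% solve(L_B)`, with its polar
#' decomposition `Lab = R %*% U` (U the symmetric positive-definite stretch,
#' R a rotation). The eigenvectors of U are the scaling axes.
#'
#' @param growth_a,growth_b `mean_growth` objects.
#' @param t_a Stage of species A.
#' @param t_b Stage of species B corresponding to the same common time.
#' @return An object of class `scaling_operator` with elements `Lab`, `U`,
#'   `R`, `stretches`, `axes`.
#' @export
interspecies_scaling <- function(growth_a, growth_b, t_a, t_b = t_a) {
  La <- growth_L(growth_a, t_a)
  Lb <- growth_L(growth_b, t_b)
  db <- det(Lb)
  if (abs(db) < .Machine$double.eps) {
    abort("species B growth tensor is singular", class = "morphodyn_value_error")
  }
  Lab <- La %*% solve(Lb)
  M2 <- t(Lab) %*% Lab
  e <- eigen(M2, symmetric = TRUE)
  U <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  R <- Lab %*% solve(U)
  structure(list(Lab = Lab, U = U, R = R,
                 stretches = sqrt(pmax(e$values, 0)), axes = e$vectors,
                 t_a = t_a, t_b = t_b),
            class = "scaling_operator")
}

#' @export
print.scaling_operator <- function(x, ...) {
  cat("<scaling_operator> stretches ", paste(signif(x$stretches, 4), collapse = ", "),
      "; rotation ", signif(atan2(x$R[2L, 1L], x$R[1L, 1L]) * 180 / pi, 3), " deg\n", sep = "")
  invisible(x)
}

#' Transform arbitrary physical points into xi coordinates
#'
#' Applies the rescaling xi = L^{-1}(t) (p - xbar(t)) to any point set given
#' in the species' physical frame at stage t (e.g. coordinates of gene
#' expression signals), putting them on the species-size-free scale.
#'
#' @param points Data frame or matrix with columns `pd_um`, `ap_um` (or two
#'   numeric columns).
#' @param growth A `mean_growth` object.
#' @param t Stage at which the points were measured.
#' @return Tibble with columns `xi_pd`, `xi_ap`.
#' @export
transform_points_to_xi <- function(points, growth, t) {
  p <- if (is.data.frame(points) && all(c("pd_um", "ap_um") %in% names(points))) {
    cbind(points$pd_um, points$ap_um)
  } else {
    as_points(points)
  }
  L <- growth_L(growth, t)
  p0 <- evaluate_map(growth$map, matrix(growth$center, 1L, 2L), t)[1L, ]
  xb <- growth_xbar(growth, t)
  xi <- sweep(p, 2L, p0 + xb) %*% t(solve(L))
  tibble::tibble(xi_pd = xi[, 1L], xi_ap = xi[, 2L])
}
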