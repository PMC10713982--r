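test_that("mean deformation gradient is exact for affine maps and converges", {
  out <- tissue_outline(reference_outline_xi() * 300)
  A <- matrix(c(1.8, 0.2, -0.3, 1.1), 2, 2)
  aff <- analytic_map(function(X, t) X %*% t(A),
                      jac_fn = function(X, t) array(rep(A, nrow(X)), c(2, 2, nrow(X))),
                      stage_range = c(0, 1), outline = out)
  expect_equal(mean_deformation_gradient(aff, 1, n_grid = 8L), A, tolerance = 1e-12)
  expect_equal(mean_deformation_gradient(aff, 1, n_grid = 40L), A, tolerance = 1e-12)

  id <- analytic_map(function(X, t) X, stage_range = c(0, 1), outline = out)
  expect_equal(mean_deformation_gradient(id, 0.5), diag(2), tolerance = 1e-12)

  # spatially varying field: coarse grid within 1e-4 relative of a finer one
  map <- flow_species_map(n_steps = 60L)
  Fc <- mean_deformation_gradient(map, 1, n_grid = 40L)
  Ff <- mean_deformation_gradient(map, 1, n_grid = 120L)
  expect_lt(max(abs(Fc - Ff)) / max(abs(Ff)), 1e-3)
})

test_that("uniform growth and pure translation produce static xi", {
  m <- uniform_growth_map(rates = c(0.9, 0.4))
  dec <- decompose(m, stages = seq(0, 1, length.out = 7), n_quad = 13,
                   seed_spacing = 0.15)
  drift <- dec$xi$traj - dec$xi$traj[, , rep(1, 7)]
  expect_all_lt(drift, 1e-10)

  shift <- analytic_map(function(X, t) X + t * matrix(c(120, -60), nrow(X), 2, byrow = TRUE),
                        stage_range = c(0, 1),
                        outline = tissue_outline(reference_outline_xi() * 300))
  dec2 <- decompose(shift, stages = seq(0, 1, length.out = 5), n_quad = 13,
                    seed_spacing = 0.15)
  drift2 <- dec2$xi$traj - dec2$xi$traj[, , rep(1, 5)]
  expect_all_lt(drift2, 1e-8)
})

test_that("recombining growth and rescaled dynamics reproduces the map", {
  map <- flow_species_map(n_steps = 80L)
  dec <- decompose(map, stages = seq(0, 1, length.out = 9), n_quad = 13,
                   seed_spacing = 0.1)
  g <- dec$growth
  truth_all <- morphodyn:::phi_hat_traj(g, dec$xi$xi0 * g$C0, g$stages)
  for (s in seq_along(g$stages)) {
    rec <- dec$xi$traj[, , s] %*% t(g$L[, , s])
    rec <- sweep(rec, 2, g$xbar[s, ], "+")
    expect_all_lt(rec - truth_all[, , s], 1e-9)
  }
})

test_that("xi trajectories agree with integrating the xi velocity field", {
  map <- flow_species_map(n_steps = 120L)
  stages <- seq(0, 1, length.out = 41)
  dec <- decompose(map, stages = stages, n_quad = 17, seed_spacing = 0.25)
  v <- xi_velocity(dec$xi, stages = stages[2:40], n_eps = 32)
  # forward integration of the velocity field from the seeds
  xi_int <- dec$xi$xi0
  h <- diff(stages)[1]
  for (s in 2:40) {
    xi_int <- xi_int + h * v[, , s - 1]
  }
  # compare with the decomposed trajectory at the second-to-last stage;
  # the bound reflects the first-order time stepping of the oracle
  disp <- max(abs(dec$xi$traj[, , 40] - dec$xi$xi0))
  expect_lt(max(abs(xi_int - dec$xi$traj[, , 40])), 0.05 * disp)
})

test_that("the 1D closed form is recovered for an embedded growth profile", {
  # x1 = X1 (1 + t (a0 + a1 X1^2)), x2 = X2 on a symmetric rectangle: the
  # centroid stays at the origin so the centroid term vanishes, and the
  # velocity reduces to dxi/dt = (S_X - S) xi with closed-form tensors
  a0 <- 0.5; a1 <- 2e-6
  w <- 300; h <- 150
  rect <- rbind(c(-w, -h), c(w, -h), c(w, h), c(-w, h))
  f <- function(X, t) cbind(X[, 1] * (1 + t * (a0 + a1 * X[, 1]^2)), X[, 2])
  jac <- function(X, t) {
    n <- nrow(X)
    J <- array(0, c(2, 2, n))
    J[1, 1, ] <- 1 + t * (a0 + 3 * a1 * X[, 1]^2)
    J[2, 2, ] <- 1
    J
  }
  m <- analytic_map(f, jac, stage_range = c(0, 1), outline = tissue_outline(rect))
  stages <- seq(0, 1, length.out = 11)
  dec <- decompose(m, stages = stages, n_quad = 20, seed_spacing = 0.2)
  s_idx <- 6L
  t <- stages[s_idx]
  v <- suppressWarnings(xi_velocity(dec$xi, stages = t, n_eps = 16))

  # closed-form comparison, sharing the quadrature lattice's X1^2 mean
  qp <- morphodyn:::quad_points(rect, 20)
  m2 <- sum(qp$points[, 1]^2 * qp$weights) / sum(qp$weights)
  abar <- a0 + 3 * a1 * m2
  Fbar11 <- 1 + t * abar
  Sbar <- abar / Fbar11
  X1 <- dec$xi$xi0[, 1] * dec$growth$C0
  G11 <- 1 + t * (a0 + a1 * X1^2)
  SX <- (a0 + a1 * X1^2) / G11
  xi1 <- dec$xi$traj[, 1, s_idx]
  expected <- (SX - Sbar) * xi1
  expect_all_lt(v[, 1, 1] - expected, 1e-6)
  expect_all_lt(v[, 2, 1], 1e-6)
})

test_that("Eq-13 evaluation matches trajectory differencing at second order", {
  map <- flow_species_map(n_steps = 120L)
  dev_at <- function(S) {
    stages <- seq(0, 1, length.out = S)
    dec <- decompose(map, stages = stages, n_quad = 15, seed_spacing = 0.3)
    mid <- (S + 1) %/% 2
    v <- xi_velocity(dec$xi, stages = stages[mid], n_eps = 32)
    fd <- (dec$xi$traj[, , mid + 1] - dec$xi$traj[, , mid - 1]) /
      (stages[mid + 1] - stages[mid - 1])
    max(abs(v[, , 1] - fd))
  }
  d1 <- dev_at(11L)
  d2 <- dev_at(21L)
  expect_lt(d2, d1)                      # shrinks under refinement
  expect_gt(d1 / d2, 2.5)               # at roughly second order
})

test_that("stage-grid boundaries fall back to one-sided differences", {
  m <- uniform_growth_map()
  dec <- decompose(m, stages = seq(0, 1, length.out = 5), n_quad = 9,
                   seed_spacing = 0.3)
  expect_warning(xi_velocity(dec$xi, stages = 0, n_eps = 4),
                 class = "morphodyn_boundary_warning")
})

test_that("star-domain identity holds and converges at second order", {
  out <- tissue_outline(reference_outline_xi() * 300)
  A <- matrix(c(1.5, 0.2, -0.1, 1.2), 2, 2)
  aff <- analytic_map(function(X, t) X %*% t(A),
                      jac_fn = function(X, t) array(rep(A, nrow(X)), c(2, 2, nrow(X))),
                      stage_range = c(0, 1), outline = out)
  X <- rbind(c(100, 50), c(-80, -60))
  expect_all_lt(star_domain_identity_check(aff, X, 1, n_eps = 4), 1e-9)

  map <- flow_species_map(n_steps = 200L)
  ring <- outline_ring(initial_outline(map))
  lat <- morphodyn:::lattice_in_polygon(ring * 0.8, 60)
  Xs <- cbind(lat$x, lat$y)[seq(1, nrow(lat), by = 7), ]
  r64 <- star_domain_identity_check(map, Xs, 0.9, n_eps = 64)
  expect_all_lt(r64, 1e-5)

  r8 <- max(star_domain_identity_check(map, Xs, 0.9, n_eps = 8, rule = "midpoint"))
  r16 <- max(star_domain_identity_check(map, Xs, 0.9, n_eps = 16, rule = "midpoint"))
  expect_equal(r8 / r16, 4, tolerance = 0.5)

  # a map that moves the origin fails the raw identity; recentring repairs it
  shift <- analytic_map(function(X, t) X %*% t(A) + t * matrix(c(200, 0), nrow(X), 2, byrow = TRUE),
                        jac_fn = function(X, t) array(rep(A, nrow(X)), c(2, 2, nrow(X))),
                        stage_range = c(0, 1), outline = out)
  raw <- star_domain_identity_check(shift, X, 1, n_eps = 16, recenter = FALSE)
  fixed <- star_domain_identity_check(shift, X, 1, n_eps = 16, recenter = TRUE)
  expect_gt(min(raw), 10)
  expect_all_lt(fixed, 1e-9)

  # segments leaving the domain are refused
  expect_error(star_domain_identity_check(map, matrix(c(5 * 400, 0), 1, 2), 0.5),
               class = "morphodyn_star_error")
})

test_that("pseudo-maps are exact for the same species and flag foreign seeds", {
  map <- flow_species_map(n_steps = 80L)
  dec <- decompose(map, stages = seq(0, 1, length.out = 7), n_quad = 13,
                   seed_spacing = 0.1)
  xi0 <- dec$xi$xi0[seq(1, nrow(dec$xi$xi0), by = 11), , drop = FALSE]
  t <- dec$xi$stages[5]
  ps <- pseudo_map(dec$growth, dec$xi, xi0, t, t)
  truth <- evaluate_map(map, sweep(xi0 * dec$growth$C0, 2, dec$growth$center, "+"), t)
  expect_all_lt(cbind(ps$pd_um, ps$ap_um) - truth, 1e-9)
  far <- pseudo_map(dec$growth, dec$xi, rbind(xi0, c(10, 10)), t, t)
  expect_false(far$valid[nrow(far)])
  expect_true(all(far$valid[-nrow(far)]))
})

test_that("interspecies scaling operators decompose into stretch and rotation", {
  m <- uniform_growth_map(rates = c(0.8, 0.5))
  dec <- decompose(m, stages = seq(0, 1, length.out = 5), n_quad = 9, seed_spacing = 0.3)
  op <- interspecies_scaling(dec$growth, dec$growth, 0.5)
  expect_equal(op$Lab, diag(2), tolerance = 1e-9)
  expect_equal(op$U, diag(2), tolerance = 1e-9)
  expect_equal(op$R, diag(2), tolerance = 1e-9)

  set.seed(4)
  for (i in 1:5) {
    Lb <- diag(2) + matrix(rnorm(4, sd = 0.2), 2, 2)
    if (det(Lb) <= 0.1) next
    ga <- dec$growth; gb <- dec$growth
    gb$L[, , 3] <- Lb
    ga$L[, , 3] <- diag(c(2, 1)) %*% Lb
    op2 <- interspecies_scaling(ga, gb, dec$growth$stages[3])
    expect_equal(op2$Lab, diag(c(2, 1)), tolerance = 1e-10)
    expect_equal(op2$R %*% op2$U, op2$Lab, tolerance = 1e-12)
    # symmetric square-root oracle via matrix power series
    M2 <- t(op2$Lab) %*% op2$Lab
    sq <- with(eigen(M2, symmetric = TRUE),
               vectors %*% diag(sqrt(values)) %*% t(vectors))
    expect_equal(op2$U, sq, tolerance = 1e-12)
    expect_equal(t(op2$R) %*% op2$R, diag(2), tolerance = 1e-12)
    expect_equal(det(op2$R), 1, tolerance = 1e-12)
  }
})

test_that("arbitrary point sets transform into xi coordinates", {
  m <- uniform_growth_map(rates = c(0.6, 0.6))
  dec <- decompose(m, stages = seq(0, 1, length.out = 5), n_quad = 11, seed_spacing = 0.2)
  g <- dec$growth
  t <- 0.5
  ctr_pt <- morphodyn:::growth_xbar(g, t) +
    evaluate_map(m, matrix(g$center, 1, 2), t)[1, ]
  expect_all_lt(as.matrix(transform_points_to_xi(matrix(ctr_pt, 1, 2), g, t)), 1e-9)

  # under uniform isotropic growth an advected expression domain has a
  # time-invariant xi footprint
  set.seed(2)
  dom0 <- matrix(rnorm(40, sd = 60), 20, 2)
  xi_a <- transform_points_to_xi(evaluate_map(m, dom0, 0), g, 0)
  xi_b <- transform_points_to_xi(evaluate_map(m, dom0, 1), g, 1)
  expect_all_lt(as.matrix(xi_a) - as.matrix(xi_b), 1e-9)
})

test_that("rotating the physical frame rotates L and preserves xi patterns", {
  map <- flow_species_map(n_steps = 80L)
  q <- 0.4
  Q <- morphodyn:::rot2(q)
  ring_rot <- outline_ring(initial_outline(map)) %*% Q   # rotated by -q... consistent frame
  rot <- conjugate_map(map, scale = 1, warp = c(1, 0), rotation = q,
                       outline = tissue_outline(outline_ring(initial_outline(map)) %*% t(Q)))
  stages <- seq(0, 1, length.out = 6)
  dec <- decompose(map, stages = stages, n_quad = 21, seed_spacing = 0.15)
  dec_r <- decompose(rot, stages = stages, n_quad = 21, seed_spacing = 0.15)
  s <- 4L
  expect_equal(dec_r$growth$L[, , s], Q %*% dec$growth$L[, , s] %*% t(Q),
               tolerance = 0.03)
  xi0 <- dec$xi$xi0[seq(1, nrow(dec$xi$xi0), by = 13), , drop = FALSE]
  xi_plain <- xi_at(dec$xi, xi0, stages[s])[, , 1]
  xi_rot <- xi_at(dec_r$xi, xi0 %*% t(Q), stages[s])[, , 1]
  expect_lt(max(abs(xi_rot - xi_plain %*% t(Q))), 2e-2)
})
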