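test_that("composition chains interval maps and respects boundaries", {
  id <- affine_pairs(diag(2), c(0, 0), n = 20, t0 = 0, t1 = 1)
  id2 <- id
  id2$stage_start <- 1; id2$stage_end <- 2; id2$interval <- 2L
  fm <- compose_maps(list(fit_interval_map(id), fit_interval_map(id2)))
  X <- matrix(c(15, -20, 40, 5), 2, 2, byrow = TRUE)
  for (t in c(0, 0.4, 1, 1.7, 2)) {
    expect_equal(evaluate_map(fm, X, t), X, tolerance = 1e-8)
  }

  d1 <- affine_pairs(2 * diag(2), c(0, 0), n = 20, t0 = 0, t1 = 1)
  d2 <- affine_pairs(3 * diag(2), c(0, 0), n = 20, t0 = 1, t1 = 2, scale = 200)
  d2$interval <- 2L
  fm6 <- compose_maps(list(fit_interval_map(d1), fit_interval_map(d2)))
  expect_equal(evaluate_map(fm6, X, 2), 6 * X, tolerance = 1e-6)
  # boundary consistency: end of interval 1 equals input of interval 2 exactly
  expect_identical(evaluate_map(fm6, X, 1),
                   morphodyn:::im_eval(fm6$interval_maps[[1]], X))

  d_gap <- d2
  d_gap$stage_start <- 1.5
  expect_error(compose_maps(list(fit_interval_map(d1), fit_interval_map(d_gap))),
               class = "morphodyn_composition_error")
})

test_that("deformation gradients match analytic and finite-difference oracles", {
  # identity
  id <- analytic_map(function(X, t) X, stage_range = c(0, 1))
  expect_equal(deformation_gradient(id, matrix(c(1, 2), 1, 2), 0.5)[, , 1],
               diag(2), tolerance = 1e-6)

  # x1 = X1 + 0.1 X1^2, x2 = X2 -> F analytic
  m <- analytic_map(function(X, t) cbind(X[, 1] + 0.1 * X[, 1]^2, X[, 2]),
                    stage_range = c(0, 1), fd_step = 1e-4)
  X <- matrix(c(2, 5), 1, 2)
  expect_equal(deformation_gradient(m, X, 0)[, , 1],
               matrix(c(1 + 0.2 * 2, 0, 0, 1), 2, 2), tolerance = 1e-6)

  # fitted synthetic map: analytic kernel Jacobian vs central differences,
  # second-order in h (checked at h and h/2)
  map <- flow_species_map(n_steps = 60L)
  d <- map_pairs(map, 0, 0.5, n = 120, sigma = 5, seed = 3)
  im <- suppressWarnings(fit_interval_map(d))
  Xs <- matrix(c(50, 40, -80, -30, 10, -60), 3, 2, byrow = TRUE)
  J <- morphodyn:::im_jac(im, Xs)
  fd_jac <- function(h) {
    out <- array(NA_real_, dim = c(2, 2, nrow(Xs)))
    for (d2 in 1:2) {
      e <- c(0, 0); e[d2] <- h
      fp <- morphodyn:::im_eval(im, sweep(Xs, 2, e, "+"))
      fm <- morphodyn:::im_eval(im, sweep(Xs, 2, e))
      out[1, d2, ] <- (fp[, 1] - fm[, 1]) / (2 * h)
      out[2, d2, ] <- (fp[, 2] - fm[, 2]) / (2 * h)
    }
    out
  }
  err_h <- max(abs(J - fd_jac(0.2)))
  err_h2 <- max(abs(J - fd_jac(0.1)))
  expect_lt(err_h / max(abs(J)), 1e-6)
  expect_lt(err_h2, err_h)
})

test_that("orientation is preserved on a dense grid of a fitted map", {
  map <- flow_species_map(n_steps = 60L)
  grid <- stage_grid("s", seq(0, 1, length.out = 5))
  fm <- fit_species(map, grid, n_per_interval = 120, sigma = 5, seed = 6)
  ring <- outline_ring(initial_outline(map))
  lat <- morphodyn:::lattice_in_polygon(ring * 0.9, 30)
  F <- deformation_gradient(fm, cbind(lat$x, lat$y), 1)
  dets <- F[1, 1, ] * F[2, 2, ] - F[1, 2, ] * F[2, 1, ]
  expect_true(all(dets > 0))
})

test_that("local deformation summaries decompose F correctly", {
  s <- local_deformation_summary(diag(2))
  expect_equal(s$area_ratio, 1)
  expect_equal(s$anisotropy, 0)
  expect_false(s$orientation_defined)

  s2 <- local_deformation_summary(diag(c(2, 1)))
  expect_equal(s2$area_ratio, 2)
  expect_equal(s2$anisotropy, log(2))
  expect_equal(s2$orientation, 0, tolerance = 1e-9)

  R45 <- morphodyn:::rot2(pi / 4)
  s3 <- local_deformation_summary(R45 %*% diag(c(2, 1)))
  expect_equal(s3$area_ratio, 2, tolerance = 1e-12)
  expect_equal(s3$anisotropy, log(2), tolerance = 1e-12)
  expect_equal(s3$orientation, pi / 4, tolerance = 1e-9)

  expect_error(local_deformation_summary(diag(c(-1, 1))),
               class = "morphodyn_tensor_error")
})

test_that("map inversion recovers initial positions", {
  A <- matrix(c(2, 0.3, -0.2, 1.5), 2, 2)
  aff <- analytic_map(function(X, t) X %*% t(A),
                      jac_fn = function(X, t) array(rep(A, nrow(X)), c(2, 2, nrow(X))),
                      stage_range = c(0, 1),
                      outline = tissue_outline(reference_outline_xi() * 200))
  x <- matrix(c(100, 50, -40, 80), 2, 2, byrow = TRUE)
  expect_equal(invert_map(aff, x, 1), x %*% t(solve(A)), tolerance = 1e-10,
               ignore_attr = TRUE)

  map <- flow_species_map(n_steps = 80L)
  set.seed(9)
  lat <- morphodyn:::lattice_in_polygon(outline_ring(initial_outline(map)) * 0.85, 45)
  X0 <- cbind(lat$x, lat$y)[sample.int(nrow(lat), 100), ]
  x1 <- evaluate_map(map, X0, 0.8)
  Xb <- invert_map(map, x1, 0.8)
  expect_all_lt(evaluate_map(map, Xb, 0.8) - x1, 1e-6)
})

test_that("bootstrap replicates of noise-free affine data agree with truth", {
  expect_equal(eval(formals(bootstrap_maps)$B), 150L)
  A <- matrix(c(1.3, 0.1, 0, 0.8), 2, 2)
  d <- affine_pairs(A, c(5, -3), n = 60)
  class(d) <- c("interval_data", class(d))
  boots <- bootstrap_maps(d, B = 8, seed = 1)
  X <- matrix(c(20, -30, 50, 10), 2, 2, byrow = TRUE)
  truth <- X %*% t(A) + matrix(c(5, -3), 2, 2, byrow = TRUE)
  for (b in boots) expect_all_lt(evaluate_map(b, X, 1) - truth, 1e-6)
  # reproducibility
  boots2 <- bootstrap_maps(d, B = 8, seed = 1)
  expect_equal(evaluate_map(boots[[3]], X, 1), evaluate_map(boots2[[3]], X, 1))
})
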