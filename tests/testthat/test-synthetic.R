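test_that("the archetype flow vanishes when all strengths are zero", {
  f0 <- archetype_flow(0, 0, 0)
  set.seed(1)
  xi <- matrix(runif(40, -0.8, 0.8), 20, 2)
  expect_equal(max(abs(f0$v(xi, 0.3))), 0)
  expect_equal(max(abs(f0$dv(xi, 0.3))), 0)
  expect_error(archetype_flow(-0.1), class = "morphodyn_value_error")
})

test_that("the A-P drift moves posterior cells toward anterior", {
  f <- archetype_flow(ap_asymmetry = 0.5, pd_nonuniformity = 0,
                      boundary_swirl = 0)
  ring <- reference_outline_xi()
  lat <- morphodyn:::lattice_in_polygon(ring, 0.1)
  inside_bump <- (lat$x / 1.05)^2 + (lat$y / 0.75)^2 < 1
  posterior <- lat$y < 0 & inside_bump
  v <- f$v(cbind(lat$x, lat$y)[posterior, ], 0)
  expect_true(all(v[, 2] > 0))
  expect_gt(mean(v[, 2]), 0)
})

test_that("flow Jacobians match finite differences of the field", {
  f <- archetype_flow()
  set.seed(3)
  xi <- matrix(runif(20, -0.6, 0.6), 10, 2)
  a <- f$dv(xi, 0)
  h <- 1e-6
  fd1 <- (f$v(cbind(xi[, 1] + h, xi[, 2]), 0) - f$v(cbind(xi[, 1] - h, xi[, 2]), 0)) / (2 * h)
  fd2 <- (f$v(cbind(xi[, 1], xi[, 2] + h), 0) - f$v(cbind(xi[, 1], xi[, 2] - h), 0)) / (2 * h)
  expect_equal(a[, 1:2], fd1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(a[, 3:4], fd2, tolerance = 1e-6, ignore_attr = TRUE)
  for (g in list(flow_proximal(edge = 0.1), flow_reverse_ap(),
                 flow_band_drift(), flow_proximal_reversal(edge = 0.1))) {
    ag <- g$dv(xi, 0)
    gd1 <- (g$v(cbind(xi[, 1] + h, xi[, 2]), 0) - g$v(cbind(xi[, 1] - h, xi[, 2]), 0)) / (2 * h)
    gd2 <- (g$v(cbind(xi[, 1], xi[, 2] + h), 0) - g$v(cbind(xi[, 1], xi[, 2] - h), 0)) / (2 * h)
    expect_equal(ag[, 1:2], gd1, tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(ag[, 3:4], gd2, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("trajectories started inside the outline remain inside", {
  map <- flow_species_map(n_steps = 100L)
  ring <- outline_ring(initial_outline(map))
  lat <- morphodyn:::lattice_in_polygon(ring * 0.98, 40)
  pos <- map_trajectory(map, cbind(lat$x, lat$y), seq(0, 1, length.out = 6))
  xi_ring <- ring / map$C0
  for (s in 1:6) {
    xi <- morphodyn:::slice3(pos, s) %*% t(solve(map$L_fn(seq(0, 1, length.out = 6)[s]))) # nolint
    expect_true(all(morphodyn:::points_in_poly(xi, xi_ring)))
  }
})

test_that("species construction satisfies its defining identities", {
  # no flow, isotropic L = C0 I, no drift: the map is the identity
  still <- make_species(archetype_flow(0, 0, 0),
                        species_spec("s", 400, growth_rates = c(0, 0), n_steps = 20L))
  X <- matrix(c(100, -50, -200, 80), 2, 2, byrow = TRUE)
  expect_all_lt(evaluate_map(still, X, 0.7) - X, 1e-12)

  # two species built from one flow share their xi trajectories exactly
  flow <- archetype_flow()
  mA <- make_species(flow, species_spec("A", 400, warp = c(1, 0), n_steps = 50L))
  mB <- make_species(flow, species_spec("B", 800, warp = c(2, 5), n_steps = 50L))
  xi0 <- matrix(c(0.3, -0.2, -0.4, 0.1), 2, 2, byrow = TRUE)
  tau <- 0.6
  xiA <- evaluate_map(mA, xi0 * 400, tau) %*% t(solve(mA$L_fn(tau)))
  xiB <- evaluate_map(mB, xi0 * 800, 2 * tau + 5) %*% t(solve(mB$L_fn(tau)))
  expect_all_lt(xiA - xiB, 1e-8)
})

test_that("a planted divergence separates the species only after onset", {
  tau_star <- 0.5
  flow <- archetype_flow()
  mA <- make_species(flow, species_spec("A", 400, warp = c(1, 0), n_steps = 60L))
  fB <- flow_with_divergence(flow, flow_reverse_ap(1), onset = tau_star, ramp = 0.05)
  mB <- make_species(fB, species_spec("B", 400, warp = c(1, 0), n_steps = 60L))
  xi0 <- matrix(c(0.2, -0.3, -0.3, 0.2, 0.1, 0.4), 3, 2, byrow = TRUE)
  X <- xi0 * 400
  taus <- seq(0.1, 0.9, by = 0.1)
  trA <- map_trajectory(mA, X, taus)
  trB <- map_trajectory(mB, X, taus)
  delta <- apply(abs(trA - trB), 3, max)
  expect_all_lt(delta[taus <= tau_star], 1e-6)
  late <- delta[taus > tau_star + 0.05]
  expect_true(all(diff(late) > 0))
  expect_gt(max(late), 1)
})

test_that("spot sampling is exact at zero noise and byte-reproducible", {
  map <- flow_species_map(n_steps = 60L)
  grid <- stage_grid("s", seq(0, 1, length.out = 4))
  des0 <- measurement_design(interval_counts = c(25, 30, 20), noise_sigma = 0, seed = 9)
  spots <- sample_spots(map, des0, grid)
  one <- spots[spots$individual_id == "ind02" & spots$spot_id == "s004", ]
  X0 <- invert_map(map, cbind(one$pd_um[1], one$ap_um[1]), one$stage[1])
  expect_all_lt(evaluate_map(map, X0, one$stage[2]) - cbind(one$pd_um[2], one$ap_um[2]),
                1e-6)

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  des <- measurement_design(interval_counts = c(25, 30, 20), noise_sigma = 7, seed = 9)
  write_spot_table(sample_spots(map, des, grid), f1)
  write_spot_table(sample_spots(map, des, grid), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("decomposing a generated species recovers its structure", {
  map <- flow_species_map(n_steps = 100L)
  stages <- seq(0, 1, length.out = 7)
  # refinement oracle for the average growth tensor
  dec <- decompose(map, stages = stages, n_quad = 41, seed_spacing = 0.2)
  dec_fine <- decompose(map, stages = stages, n_quad = 123, seed_spacing = 0.2)
  expect_lt(max(abs(dec$growth$L - dec_fine$growth$L)) / max(abs(dec_fine$growth$L)),
            1e-3)
  # xi velocity consistent with trajectory slopes at mid-grid
  v <- xi_velocity(dec$xi, stages = stages[4], n_eps = 8)
  fd <- (dec$xi$traj[, , 5] - dec$xi$traj[, , 3]) / (stages[5] - stages[3])
  expect_lt(sqrt(mean((v[, , 1] - fd)^2)), 2e-2)
})
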