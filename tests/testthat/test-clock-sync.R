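shared_pair <- function(div = NULL, n_steps = 80L, S = 13L) {
  flow <- archetype_flow()
  mA <- make_species(flow, species_spec("A", 400, warp = c(1, 0), n_steps = n_steps))
  fB <- if (is.null(div)) flow else
    flow_with_divergence(flow, div$field, onset = div$onset, ramp = div$ramp %||% 0.05)
  mB <- make_species(fB, species_spec("B", 800, warp = c(1, 0), n_steps = n_steps))
  stages <- seq(0, 1, length.out = S)
  list(
    a = decompose(mA, stages = stages, n_quad = 13, seed_spacing = 0.12)$xi,
    b = decompose(mB, stages = stages, n_quad = 13, seed_spacing = 0.12)$xi,
    stages = stages
  )
}

test_that("overlap seeds are the lattice of the outline intersection", {
  p <- shared_pair(S = 5L)
  om <- overlap_region(p$a, p$a)
  expect_equal(nrow(om), nrow(p$a$xi0))

  # seed count tracks intersection area times lattice density
  om_ab <- overlap_region(p$a, p$b, spacing = 0.05)
  area <- morphodyn:::poly_area(p$a$outline_xi)   # same outline shape in xi
  expect_equal(nrow(om_ab), area / 0.05^2, tolerance = 0.08)

  shifted <- p$b
  shifted$outline_xi <- p$b$outline_xi + 10
  expect_error(overlap_region(p$a, shifted), class = "morphodyn_overlap_error")
})

test_that("trajectory distance is a pseudometric on snapshots", {
  p <- shared_pair(S = 5L)
  om <- overlap_region(p$a, p$b)
  expect_equal(trajectory_distance(p$a, p$a, 0.5, 0.5, om), 0)
  expect_equal(trajectory_distance(p$a, p$b, 0.5, 0.75, om),
               trajectory_distance(p$b, p$a, 0.75, 0.5, om))

  # snapshots offset by a constant vector: the distance is the offset length
  off <- p$a
  off$traj[, 1, ] <- off$traj[, 1, ] + 0.03
  off$traj[, 2, ] <- off$traj[, 2, ] - 0.04
  om_a <- overlap_region(p$a, p$a)
  expect_equal(trajectory_distance(p$a, off, 0.5, 0.5, om_a), 0.05, tolerance = 1e-12)

  # triangle inequality across three distinct flows at matched stages
  extra <- shared_pair(div = list(field = flow_reverse_ap(1), onset = 0), S = 5L)
  dab <- trajectory_distance(p$a, p$b, 0.75, 0.75, om)
  dac <- trajectory_distance(p$a, extra$b, 0.75, 0.75, om)
  dcb <- trajectory_distance(extra$b, p$b, 0.75, 0.75, om)
  expect_lte(dac, dab + dcb + 1e-12)

  # species sharing one flow coincide at matched stages
  expect_lt(dab, 1e-6)
})

test_that("the distance matrix has a zero diagonal for identical dynamics", {
  p <- shared_pair(S = 7L)
  dm <- distance_matrix(p$a, p$a)
  expect_all_lt(diag(dm$delta), 1e-12)
  expect_true(all(dm$delta >= 0))
})

test_that("composite maps recover a planted linear stage warp", {
  flow <- archetype_flow()
  mA <- make_species(flow, species_spec("A", 400, warp = c(1, 0), n_steps = 80L))
  a <- 2; b <- 0.3
  mB <- make_species(flow, species_spec("B", 800, warp = c(a, b), n_steps = 80L))
  stA <- seq(0, 1, length.out = 15)
  stB <- seq(b, a + b, length.out = 15)
  dA <- decompose(mA, stages = stA, n_quad = 13, seed_spacing = 0.12)$xi
  dB <- decompose(mB, stages = stB, n_quad = 13, seed_spacing = 0.12)$xi
  dm <- distance_matrix(dA, dB)
  cm <- composite_stage_maps(dm)
  # the ridge follows the warp within one grid step
  expect_all_lt(cm$ab$t_target - (a * cm$ab$t_source + b), diff(stB)[1] + 1e-9)
  lf <- fit_linear_correspondence(cm$ab)
  expect_equal(lf$slope, a, tolerance = 0.02)
  expect_lt(abs(lf$intercept - b), diff(stB)[1])
  vr <- validity_range(cm, tol = 1)
  expect_equal(vr$k_a, length(stA))
  expect_equal(vr$k_b, length(stB))
})

test_that("argmin ties break toward the earlier stage", {
  dm <- structure(list(delta = matrix(c(0, 1, 0, 1, 1, 0, 1, 0), 2, 4, byrow = TRUE),
                       stages_a = c(1, 2), stages_b = c(10, 20, 30, 40),
                       omega = tibble::tibble(), species_a = "A", species_b = "B"),
                  class = "stage_distance")
  cm <- composite_stage_maps(dm)
  expect_equal(cm$ab$t_target, c(10, 20))
})

test_that("validity ends before a jump larger than the tolerance", {
  targets <- c(1, 2, 3, 6, 7, 8)   # monotone, with one 3-step jump
  delta <- outer(targets, seq_len(8), function(t, j) abs(j - t))
  dm <- structure(list(delta = delta, stages_a = as.numeric(1:6),
                       stages_b = as.numeric(1:8),
                       omega = tibble::tibble(), species_a = "A", species_b = "B"),
                  class = "stage_distance")
  cm <- composite_stage_maps(dm)
  expect_equal(cm$ab$target_index, targets)
  vr <- validity_range(cm, tol = 1)
  expect_equal(vr$k_a, 3L)
})

test_that("flow divergence splits the correspondences where it starts", {
  tau_star <- 0.6
  p <- shared_pair(div = list(field = flow_reverse_ap(1.5), onset = tau_star),
                   S = 21L)
  dm <- distance_matrix(p$a, p$b)
  cm <- composite_stage_maps(dm)
  vr <- validity_range(cm, tol = 1)
  step <- diff(p$stages)[1]
  expect_lt(abs(vr$t_a_end - tau_star), 2 * step + 1e-9)
  expect_lt(abs(vr$t_b_end - tau_star), 2 * step + 1e-9)
  # after the onset the two directions stop being mutual inverses
  late <- which(p$stages > tau_star + 2 * step)
  round_trip <- cm$ba$target_index[cm$ab$target_index[late]]
  expect_gt(max(abs(round_trip - late)), 1L)
})

test_that("linear correspondence fitting validates its input", {
  m <- tibble::tibble(t_source = 1:5, t_target = 1:5, target_index = 1:5,
                      delta_min = 0)
  class(m) <- c("stage_map", class(m))
  lf <- fit_linear_correspondence(m)
  expect_equal(lf$slope, 1)
  expect_equal(lf$intercept, 0)
  expect_error(fit_linear_correspondence(m[1:2, ]), class = "morphodyn_value_error")
})

test_that("initial-stage selection finds the planted pairing", {
  flow <- archetype_flow()
  mA <- make_species(flow, species_spec("A", 400, warp = c(1, 0), n_steps = 60L))
  off <- -0.25
  mB <- make_species(flow, species_spec("B", 800, warp = c(1, off), n_steps = 60L))
  ringA <- outline_ring(initial_outline(mA))
  paramsets <- data.frame(alpha = c(0.9, 0.9, 1, 1), beta = c(-0.05, 0.05, -0.05, 0.05))
  res <- select_initial_stages(mA, ringA, mB, outline_ring(initial_outline(mB)),
                               candidates_b = off + c(0, 0.25),
                               paramsets = paramsets,
                               theta_grid = c(-0.1, 0, 0.1),
                               n_stages = 7L, n_quad = 11, seed_spacing = 0.15)
  expect_equal(attr(res, "best"), off)
  expect_lt(res$median_eta[res$t0_b == off], res$median_eta[res$t0_b == off + 0.25])
})
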