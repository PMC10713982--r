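# Shared builders for small synthetic scenarios. Everything is generated in
# code at test time; sizes are kept desk-scale.

# spatially uniform (possibly anisotropic) growth: phi(X, t) = L(tau) X / C0
uniform_growth_map <- function(C0 = 400, rates = c(0.8, 0.5)) {
  make_species(archetype_flow(0, 0, 0),
               species_spec("uniform", C0 = C0, growth_rates = rates,
                            warp = c(1, 0), n_steps = 50L))
}

# default nonlinear single species on the frog-like scale
flow_species_map <- function(C0 = 400, warp = c(1, 0), flow = archetype_flow(),
                             n_steps = 120L) {
  make_species(flow, species_spec("syn", C0 = C0, warp = warp, n_steps = n_steps))
}

# exact affine pairs for interval [t0, t1]
affine_pairs <- function(A, b, n = 40, seed = 1, t0 = 0, t1 = 1, scale = 100) {
  set.seed(seed)
  X <- matrix(stats::runif(2 * n, -scale, scale), n, 2L)
  x <- X %*% t(A) + matrix(b, n, 2L, byrow = TRUE)
  tibble::tibble(interval = 1L, stage_start = t0, stage_end = t1,
                 X_pd = X[, 1L], X_ap = X[, 2L], x_pd = x[, 1L], x_ap = x[, 2L])
}

# one-interval dataset from an analytic map, optional noise on the end points
map_pairs <- function(map, t0, t1, n = 150, sigma = 0, seed = 1, scale = 0.8) {
  set.seed(seed)
  ring <- morphodyn:::outline_ring(initial_outline(map))
  ctr <- morphodyn:::poly_centroid(ring)
  ring_s <- sweep(sweep(ring, 2, ctr) * scale, 2, ctr, "+")
  half <- apply(ring_s, 2, function(v) diff(range(v)) / 2)
  i <- 0L
  X <- matrix(numeric(0), 0L, 2L)
  while (nrow(X) < n && i < 20L) {
    cand <- matrix(stats::runif(2 * 3 * n, -1, 1), ncol = 2L)
    cand <- sweep(cand %*% diag(half), 2L, ctr, "+")
    keep <- morphodyn:::points_in_poly(cand, ring_s)
    X <- rbind(X, cand[keep, , drop = FALSE])
    i <- i + 1L
  }
  X <- X[seq_len(n), , drop = FALSE]
  X0 <- invert_map(map, X, t0)
  x <- evaluate_map(map, X0, t1)
  x <- x + sigma * matrix(stats::rnorm(2 * n), n, 2L)
  tibble::tibble(interval = 1L, stage_start = t0, stage_end = t1,
                 X_pd = X[, 1L], X_ap = X[, 2L], x_pd = x[, 1L], x_ap = x[, 2L])
}

# fit a full species from sampled spots
fit_species <- function(map, grid, n_per_interval = 150, sigma = 10, seed = 1) {
  des <- measurement_design(interval_counts = rep(n_per_interval,
                                                  length(grid$stages) - 1L),
                            noise_sigma = sigma, seed = seed)
  spots <- sample_spots(map, des, grid)
  idata <- build_interval_datasets(spots, grid)
  fits <- lapply(sort(unique(idata$interval)), function(k) {
    suppressWarnings(fit_interval_map(idata[idata$interval == k, ]))
  })
  compose_maps(fits, outline = initial_outline(map))
}

expect_all_lt <- function(x, bound) expect_lt(max(abs(x)), bound)
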