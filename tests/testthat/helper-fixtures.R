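# Shared small fixtures, built in code at test time.

tiny_world <- function(seed = 1, ...) {
  make_toy_world(world_config(nx = 10, ny = 10, n_countries = 2,
                              n_admin1 = 4, n_admin2 = 8,
                              years = 2000:2003, ...), seed = seed)
}

# Simulate cluster-level binomial data directly from the geostatistical model
# on a regular grid, for fit-stage tests: one known logit-scale covariate
# (H = 1, beta = 1 by the sum-to-one constraint).
simulate_stage_data <- function(seed, nx = 12, T = 4, n_obs = 200, N = 30,
                                omega2 = 0.5, delta = 3, rho = 0.8,
                                sigma2_nug = 0.05, beta0 = 0,
                                covariate = function(x, y) -2 + 0.2 * (x - mean(x))) {
  set.seed(seed)
  cells <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(nx)))
  years <- 2000:(1999 + T)
  xc_cell <- covariate(cells[, 1], cells[, 2])
  if (omega2 > 0) {
    op <- spacetime_covariance(cells, T,
                               cov_params(omega2, delta, rho))
    Z <- st_draw(op)[, , 1]
  } else {
    Z <- matrix(0, nrow(cells), T)
  }
  oi <- sample(nrow(cells), n_obs, replace = TRUE)
  ot <- sample(T, n_obs, replace = TRUE)
  eta <- beta0 + xc_cell[oi] + Z[cbind(oi, ot)] +
    stats::rnorm(n_obs, 0, sqrt(sigma2_nug))
  d <- data.frame(N = N, x = cells[oi, 1], y = cells[oi, 2],
                  year = years[ot], country = 1L, weight_obs = 1,
                  xc = xc_cell[oi])
  d$C <- stats::rbinom(n_obs, d$N, stats::plogis(eta))
  list(data = d, cells = cells, years = years, Z = Z, xc_cell = xc_cell,
       eta_cell = function() outer(xc_cell, rep(beta0, T), "+") + Z)
}

expect_same_csv <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
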