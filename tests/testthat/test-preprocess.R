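make_seasonal_records <- function(n = 8000, amplitude = 0.5,
                                  country_offset = 0, trend = 0, sd = 1,
                                  seed = 1) {
  set.seed(seed)
  month <- sample.int(12, n, replace = TRUE)
  year <- sample(0:5, n, replace = TRUE)
  t <- year * 12L + month - 1L
  country <- sample(1:2, n, replace = TRUE)
  whz <- amplitude * sin(2 * pi * month / 12) + trend * t +
    country_offset * (country == 2) + rnorm(n, 0, sd)
  data.frame(month = month, t = t, country = country, whz = whz)
}

test_that("a constant outcome yields a null seasonal component", {
  d <- make_seasonal_records(500, amplitude = 0, sd = 0)
  d$whz <- 0.7
  fit <- fit_seasonal_model(d)
  expect_lt(seasonal_amplitude(fit), 1e-8)
  adj <- adjust_whz(d, fit)
  expect_equal(adj$whz_adj, d$whz, tolerance = 1e-8)
})

test_that("a planted seasonal signal is recovered within 10%", {
  d <- make_seasonal_records(10000, amplitude = 0.5, sd = 1)
  fit <- fit_seasonal_model(d)
  amp <- seasonal_amplitude(fit)
  expect_lt(abs(amp - 0.5) / 0.5, 0.10)

  # adjustment removes the signal: refitting the adjusted records leaves
  # residual amplitude < 10% of planted
  adj <- adjust_whz(d, fit)
  refit <- fit_seasonal_model(adj, z_col = "whz_adj")
  expect_lt(seasonal_amplitude(refit), 0.1 * 0.5)
})

test_that("country offsets are absorbed by the fixed effects, not the spline", {
  d <- make_seasonal_records(10000, amplitude = 0.3, country_offset = 1)
  fit <- fit_seasonal_model(d)
  cf <- coef(fit$gam)
  expect_equal(unname(cf["country2"]), 1, tolerance = 0.1)
  expect_lt(abs(seasonal_amplitude(fit) - 0.3) / 0.3, 0.15)
})

test_that("the fitted periodic component is continuous across the wrap", {
  d <- make_seasonal_records(6000, amplitude = 0.4)
  fit <- fit_seasonal_model(d)
  eps <- 1e-6
  expect_lt(abs(fit$seasonal(0.5 + eps) - fit$seasonal(12.5 - eps)), 1e-4)
  # periodic mean is the cycle average of the curve
  grid <- seq(0.5, 12.5, length.out = 481)[-481]
  expect_equal(fit$periodic_mean, mean(fit$seasonal(grid)))
})

test_that("adjustment is mean-preserving under uniform months", {
  set.seed(3)
  d <- data.frame(month = rep(1:12, each = 400))
  d$t <- d$month - 1L
  d$country <- 1
  d$whz <- 0.4 * sin(2 * pi * d$month / 12) + rnorm(nrow(d), 0, 0.8)
  fit <- fit_seasonal_model(d)
  adj <- adjust_whz(d, fit)
  expect_equal(mean(adj$whz_adj), mean(d$whz), tolerance = 1e-2)
})

test_that("seasonal fits serialize to JSON", {
  d <- make_seasonal_records(2000)
  fit <- fit_seasonal_model(d)
  f <- withr::local_tempfile(fileext = ".json")
  write_seasonal_fit(fit, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$periodic_mean, fit$periodic_mean, tolerance = 1e-10)
  expect_equal(back$seasonal_curve$value[1], fit$seasonal(0.5),
               tolerance = 1e-8)
})

test_that("fewer than two months is rejected", {
  d <- data.frame(month = rep(5, 20), t = 1:20, country = 1, whz = rnorm(20))
  expect_error(fit_seasonal_model(d), "two distinct")
})

test_that("polygon resampling weights behave as specified", {
  cells <- data.frame(cell = 1:12, x = rep(1:4, 3), y = rep(1:3, each = 4),
                      pop = rep(10, 12))
  # ratio 1: one pseudo-point per cell, weights sum to one
  pts <- resample_polygon(cells, ratio = 1, seed = 2)
  expect_equal(nrow(pts), 12)
  expect_equal(sum(pts$weight), 1)
  expect_true(all(pts$weight > 0))
  expect_true(all(pts$cell %in% cells$cell))

  # a single populated cell receives every point
  cells2 <- cells
  cells2$pop <- c(100, rep(0, 11))
  pts2 <- resample_polygon(cells2, ratio = 1, seed = 3)
  expect_true(all(pts2$cell == 1))

  # uniform population: empirical selection frequencies are uniform
  counts <- integer(12)
  for (s in 1:500) {
    p <- resample_polygon(cells, ratio = 2, seed = s)
    counts <- counts + tabulate(p$cell, 12)
  }
  freq <- counts / sum(counts)
  expect_lt(max(abs(freq - 1 / 12)), 0.01)

  expect_error(resample_polygon(transform(cells, pop = 0)),
               "positive population")
})

test_that("polygon expansion conserves per-polygon information weight", {
  w <- tiny_world()
  tr <- simulate_latent_truth(w, seed = 3)
  rec <- simulate_child_records(w, tr, n_clusters = 40, seed = 4)
  rec <- make_polygon_observations(rec, 0.5, seed = 5)
  rec$whz <- compute_whz(rec, w$lms)
  obs <- collapse_clusters(rec)
  expanded <- expand_polygon_obs(obs, w, ratio = 1 / 4, seed = 6)
  expect_true(all(!is.na(expanded$x)))
  # each polygon cluster-year contributes total weight 1
  poly_keys <- unique(paste(obs$cluster_id, obs$year)[obs$loc_type ==
                                                        "polygon"])
  for (k in poly_keys) {
    sel <- paste(expanded$cluster_id, expanded$year) == k
    expect_equal(sum(expanded$weight_obs[sel]), 1)
  }
  # counts are inherited, not split
  expect_true(all(expanded$N[expanded$loc_type == "pseudo"] %in% obs$N))
})
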