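test_that("world generation is deterministic and respects its invariants", {
  cfg <- world_config(nx = 10, ny = 10, n_countries = 2, n_admin1 = 4,
                      n_admin2 = 8, years = 2000:2017,
                      barren_fraction = 0.1)
  w1 <- make_toy_world(cfg, seed = 1)
  w2 <- make_toy_world(cfg, seed = 1)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  expect_equal(nrow(w1$cells), 100)

  # admin2 nests in admin1 nests in country
  by_a2 <- split(w1$cells, w1$cells$admin2)
  expect_true(all(vapply(by_a2, function(s) length(unique(s$admin1)) == 1,
                         logical(1))))
  by_a1 <- split(w1$cells, w1$cells$admin1)
  expect_true(all(vapply(by_a1, function(s) length(unique(s$country)) == 1,
                         logical(1))))
  # every non-barren cell has one admin2; barren count and zero population
  expect_true(all(!is.na(w1$cells$admin2[w1$cells$landcover != "barren"])))
  expect_equal(sum(w1$cells$landcover == "barren"), floor(0.1 * 100))
  expect_true(all(w1$cells$pop[w1$cells$landcover == "barren"] == 0))
  expect_true(all(w1$cells$pop >= 0))
  expect_true(all(w1$cells$pop_u5 <= w1$cells$pop))
})

test_that("invalid world configurations are rejected", {
  expect_error(world_config(nx = 3), "at least 4x4")
  expect_error(world_config(years = 2000), "spanning")
  expect_error(world_config(n_admin1 = 3, n_countries = 2), "multiple")
  expect_error(world_config(barren_fraction = 1), "barren_fraction")
})

test_that("latent truth sums components and hits GP marginal variance", {
  w <- tiny_world()
  tr <- simulate_latent_truth(w, seed = 5)
  # stored components sum exactly to the stored linear predictor
  st <- tr$stages$wasting
  fixed <- st$beta0 + drop(w$covariates %*% st$beta)
  recon <- st$Z + fixed + st$country_effects[w$cells$country]
  expect_equal(recon, st$eta, tolerance = 1e-12)
  # category simplex holds to machine precision
  expect_lt(max(abs(tr$p_wasting + tr$p_over + tr$p_normal - 1)), 1e-12)

  # omega2 = 0 degenerates to a deterministic field
  pr0 <- list(wasting = list(beta0 = -2, beta = c(1, 0, 0),
                             cov = cov_params(omega2 = 0, delta = 3,
                                              rho = 0.5)),
              overweight = list(beta0 = -3, beta = c(0, 1, 0),
                                cov = cov_params(omega2 = 0, delta = 3,
                                                 rho = 0.5)))
  tr0 <- simulate_latent_truth(w, pr0, seed = 2)
  expect_true(all(tr0$stages$wasting$Z == 0))

  # Monte-Carlo check of the simulated marginal variance at a cell-year
  coords <- cbind(c(1, 2, 4), c(1, 3, 2))
  op <- spacetime_covariance(coords, 2, cov_params(omega2 = 1, delta = 2,
                                                   rho = 0.5))
  set.seed(99)
  draws <- dbmgeo:::st_draw(op, n_draws = 5000)
  v <- var(draws[2, 1, ])
  expect_lt(abs(v - 1), 0.05)
  # cross-cell correlation matches the Matern entry
  r_emp <- cor(draws[1, 1, ], draws[2, 1, ])
  expect_lt(abs(r_emp - matern_correlation(sqrt(5), 2)), 0.05)
})

test_that("rho at the AR1 boundary is rejected", {
  expect_error(cov_params(rho = 1), "rho")
})

test_that("child records round-trip the planted WHZ through the LMS", {
  w <- tiny_world()
  tr <- simulate_latent_truth(w, seed = 3)
  rec <- simulate_child_records(w, tr, n_clusters = 40, seed = 4)
  z <- compute_whz(rec, w$lms)
  expect_lt(max(abs(z - rec$whz_planted)), 1e-9)
  # both LMS branches are exercised by the toy reference
  expect_setequal(unique(w$lms$L), c(0, 1))
})

test_that("category frequencies converge to the planted probabilities", {
  w <- tiny_world()
  tr <- simulate_latent_truth(w, seed = 3)
  # many clusters, amplitude 0: empirical category shares at a cell-year
  # approach the truth's simplex
  rec <- simulate_child_records(w, tr, n_clusters = 400,
                                children_per_cluster = 60,
                                seasonal_amplitude = 0, seed = 8)
  rec$whz <- compute_whz(rec, w$lms)
  cats <- classify_whz(rec$whz_base)
  ti <- match(rec$year, w$years)
  idx <- cbind(match(rec$cell, w$cells$cell), ti)
  exp_w <- tr$p_wasting[idx]
  expect_lt(abs(mean(cats == "wasted") - mean(exp_w)), 0.01)
  exp_o <- tr$p_over[idx]
  expect_lt(abs(mean(cats == "overweight") - mean(exp_o)), 0.01)
})

test_that("seasonal amplitude shifts mean WHZ between peak and trough", {
  w <- tiny_world()
  tr <- simulate_latent_truth(w, seed = 3)
  rec <- simulate_child_records(w, tr, n_clusters = 600,
                                children_per_cluster = 40,
                                seasonal_amplitude = 0.5, seed = 9)
  peak <- rec$whz_planted[rec$month == 3] - rec$whz_base[rec$month == 3]
  trough <- rec$whz_planted[rec$month == 9] - rec$whz_base[rec$month == 9]
  expect_equal(mean(peak) - mean(trough), 2 * 0.5, tolerance = 1e-10)
})

test_that("polygon conversion preserves counts and respects the fraction", {
  w <- tiny_world()
  tr <- simulate_latent_truth(w, seed = 3)
  rec <- simulate_child_records(w, tr, n_clusters = 50, seed = 4)
  rec$whz <- compute_whz(rec, w$lms)

  r0 <- make_polygon_observations(rec, 0, seed = 1)
  expect_identical(r0, rec)
  r1 <- make_polygon_observations(rec, 1, seed = 1)
  expect_true(all(is.na(r1$x)))
  expect_true(all(r1$loc_type == "polygon"))

  rh <- make_polygon_observations(rec, 0.5, seed = 1)
  o_all <- collapse_clusters(rec)
  o_half <- collapse_clusters(rh)
  expect_equal(sum(o_half$N), sum(o_all$N))
  expect_equal(sum(o_half$C_w), sum(o_all$C_w))
  expect_equal(sum(o_half$C_o), sum(o_all$C_o))
})

test_that("world layers round-trip through plain-text writers", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  write_world(w, dir)
  pop <- read_ascii_grid(file.path(dir, "pop.asc"))
  expect_equal(as.vector(t(pop)), w$cells$pop, tolerance = 1e-8)
  gj <- jsonlite::read_json(file.path(dir, "admin2.geojson"))
  expect_equal(length(gj$features), 8)
  lms <- read.csv(file.path(dir, "lms_reference.csv"))
  expect_equal(nrow(lms), nrow(w$lms))
})
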