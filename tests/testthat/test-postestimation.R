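# Minimal posterior_draws object with prescribed wasting draws.
fake_draws <- function(p_w, years, p_cond = 0.5) {
  p_o <- (1 - p_w) * p_cond
  structure(list(p_wasting = p_w, p_over = p_o, p_normal = 1 - p_w - p_o,
                 years = years, n_draws = dim(p_w)[3], seed = 0L),
            class = "posterior_draws")
}

test_that("masking hits exactly the barren or underpopulated cells", {
  land <- c("vegetated", "barren", "vegetated", "vegetated")
  pop <- c(100, 0, 5, 50)
  s <- matrix(0.2, 4, 3)
  m <- apply_mask(s, land, pop, pop_threshold = 10)
  expect_true(all(is.na(m[2:3, ])))
  expect_equal(m[c(1, 4), ], s[c(1, 4), ])
  # identity when nothing qualifies
  m2 <- apply_mask(s, rep("vegetated", 4), rep(100, 4))
  expect_identical(m2, s)
  # enumeration oracle on a random configuration
  set.seed(2)
  land_r <- sample(c("barren", "vegetated"), 50, TRUE, prob = c(0.2, 0.8))
  pop_r <- runif(50, 0, 30)
  s_r <- array(0.1, c(50, 2, 3))
  m_r <- apply_mask(s_r, land_r, pop_r)
  expect_equal(sum(is.na(m_r[, 1, 1])),
               sum(land_r == "barren" | pop_r < 10))
  expect_error(apply_mask(s, land[1:2], pop), "do not match")
})

test_that("aggregation is the population-weighted draw-level mean", {
  # two cells, one unit: hand-computed weighted mean
  p <- array(c(0.1, 0.3), c(2, 1, 4))
  dr <- fake_draws(p, years = 2017)
  est <- aggregate_draws(dr, pop_u5 = c(100, 300), membership = c(1, 1),
                         categories = "p_wasting")
  expect_equal(est$mean, 0.25)
  expect_equal(est$count, 0.25 * 400)
  # uniform prevalence is invariant to weights
  p2 <- array(0.07, c(3, 1, 5))
  est2 <- aggregate_draws(fake_draws(p2, 2017), c(10, 200, 3000), rep(7, 3),
                          categories = "p_wasting")
  expect_equal(est2$mean, 0.07)
  # national equals the population-weighted mean of its admin1 estimates
  set.seed(3)
  p3 <- array(runif(6 * 2 * 10, 0.02, 0.3), c(6, 2, 10))
  pop <- runif(6, 50, 500)
  a1 <- c(1, 1, 2, 2, 3, 3)
  dr3 <- fake_draws(p3, years = 2016:2017)
  by_a1 <- aggregate_draws(dr3, pop, a1, categories = "p_wasting")
  nat <- aggregate_draws(dr3, pop, rep(1, 6), categories = "p_wasting")
  for (yr in 2016:2017) {
    sub <- by_a1[by_a1$year == yr, ]
    expect_equal(sum(sub$mean * sub$pop_u5) / sum(sub$pop_u5),
                 nat$mean[nat$year == yr], tolerance = 1e-12)
  }
  # draw-level simplex is preserved through aggregation
  all_cats <- aggregate_draws(dr3, pop, a1)
  sums <- tapply(all_cats$mean, list(all_cats$unit, all_cats$year), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  # lower <= mean <= upper
  expect_true(all(all_cats$lower <= all_cats$mean + 1e-12))
  expect_true(all(all_cats$mean <= all_cats$upper + 1e-12))
})

test_that("zero-population units are flagged missing", {
  p <- array(0.1, c(2, 1, 3))
  est <- aggregate_draws(fake_draws(p, 2017), c(0, 0), c(1, 1),
                         categories = "p_wasting")
  expect_true(is.na(est$mean))
})

test_that("AROC closed forms hold exactly", {
  years <- 2000:2017
  # constant series: AROC identically zero, projection equals base
  p_const <- array(0.12, c(3, length(years), 5))
  a0 <- compute_aroc(p_const, years, gamma_w = 1)
  expect_equal(max(abs(a0)), 0, tolerance = 1e-10)
  proj0 <- project_prevalence(p_const[, length(years), ], a0, horizon = 8)
  expect_equal(proj0, p_const[, length(years), ], tolerance = 1e-10)

  # logit-linear series with slope 0.05/yr: AROC = 0.05 for any gamma
  p_lin <- array(NA_real_, c(2, length(years), 3))
  for (ti in seq_along(years)) {
    p_lin[, ti, ] <- plogis(-2 + 0.05 * (years[ti] - 2000))
  }
  for (g in c(0, 1, 3)) {
    expect_equal(max(abs(compute_aroc(p_lin, years, gamma_w = g) - 0.05)),
                 0, tolerance = 1e-10)
  }
  # 8-year projection shifts the logit by 0.4
  proj <- project_prevalence(p_lin[, length(years), ],
                             compute_aroc(p_lin, years, 1), horizon = 8)
  expect_equal(qlogis(proj) - qlogis(p_lin[, length(years), ]),
               array(0.4, c(2, 3)), tolerance = 1e-10)
  # horizon 0 is the identity
  expect_equal(project_prevalence(p_lin[, 18, ],
                                  compute_aroc(p_lin, years, 1), 0),
               p_lin[, 18, ], tolerance = 1e-12)

  # huge gamma concentrates all the weight on the last adjacent pair
  p_r <- array(runif(2 * 18 * 2, 0.05, 0.4), c(2, 18, 2))
  a_inf <- compute_aroc(p_r, years, gamma_w = 200)
  last_diff <- qlogis(p_r[, 18, ]) - qlogis(p_r[, 17, ])
  expect_equal(a_inf, last_diff, tolerance = 1e-3)

  # weight normalization for any gamma
  for (g in c(0, 0.7, 2, 10)) {
    W <- (years[-1] - years[1] + 1)^g
    expect_equal(sum(W / sum(W)), 1, tolerance = 1e-12)
  }
  # monotonicity of the projection in AROC
  base <- matrix(0.1, 1, 4)
  ar <- matrix(c(-0.1, 0, 0.1, 0.2), 1, 4)
  pr <- project_prevalence(base, ar, horizon = 8)
  expect_true(all(diff(pr[1, ]) > 0))

  # boundary prevalence is clamped with a warning
  p_bad <- array(c(0, 0.5), c(1, 2, 1))
  expect_warning(compute_aroc(p_bad, 2000:2001), "clamped")
})

test_that("the literal ratio AROC variant is available for audit", {
  p <- array(NA_real_, c(1, 3, 1))
  p[1, , 1] <- c(0.4, 0.2, 0.1)
  a <- compute_aroc(p, 2000:2002, gamma_w = 0, aroc_type = "ratio")
  expect_equal(a[1, 1], mean(qlogis(c(0.5, 0.5))), tolerance = 1e-12)
})

test_that("double-burden bands follow the inclusive thresholds", {
  # worked categorical statements: 6%/7% -> moderate; both >= 10% -> high
  cls <- classify_bands(c(0.06, 0.049, 0.12, 0.16, 0.04),
                        c(0.07, 0.30, 0.11, 0.17, 0.04))
  expect_equal(as.character(cls$dbm),
               c("moderate", "none", "high", "very_high", "none"))
  expect_equal(as.character(cls$over_band[2]), "[15,Inf)")
  # boundary: exactly 5% is inside the moderate band (lower edge inclusive)
  b <- classify_bands(0.05, 0.05)
  expect_equal(as.character(b$dbm), "moderate")
  b10 <- classify_bands(0.10, 0.10)
  expect_equal(as.character(b10$dbm), "high")
  expect_error(classify_bands(1.2, 0.1), "\\[0, 1\\]")
  # nesting: very_high implies high implies moderate threshold satisfaction
  expect_true(all(c(0.16, 0.17) >= 0.05))
})

test_that("the WHO wasting target check is strict at 5%", {
  expect_true(gnt_check(0.049))
  expect_false(gnt_check(0.05))
  # enumeration oracle over a synthetic surface
  set.seed(4)
  p <- runif(200, 0, 0.15)
  expect_equal(sum(gnt_check(p)), sum(p < 0.05))
})
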