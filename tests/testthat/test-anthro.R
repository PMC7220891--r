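ref1 <- data.frame(sex = c("female", "female"), age_months = c(10, 11),
                   L = c(1, 0), M = c(10, 10), S = c(0.1, 0.1))

test_that("the LMS transform evaluates both branches correctly", {
  # median maps to zero under either branch
  r <- data.frame(weight = 10, sex = "female", age = c(10, 11))
  expect_equal(compute_whz(r, ref1), c(0, 0))
  # power branch: L=1, M=10, S=0.1, x=12 -> ((12/10) - 1)/0.1 = 2
  r <- data.frame(weight = 12, sex = "female", age = 10)
  expect_equal(compute_whz(r, ref1), 2)
  # log branch: L=0, x = 10 e^0.2 -> log(x/M)/S = 2
  r <- data.frame(weight = 10 * exp(0.2), sex = "female", age = 11)
  expect_equal(compute_whz(r, ref1), 2)
  # missing reference row errors
  r <- data.frame(weight = 10, sex = "male", age = 10)
  expect_error(compute_whz(r, ref1), "no LMS reference row")
  # duplicate keys rejected
  expect_error(compute_whz(r, rbind(ref1, ref1)), "duplicate")
})

test_that("classification uses strict two-sd cutoffs", {
  expect_equal(classify_whz(c(-2.01, -2, 2, 2.5, 0)),
               c("wasted", "normal", "normal", "overweight", "normal"))
  expect_error(classify_whz(c(1, NaN)), "finite")
})

test_that("implausibility filter drops by reason and keeps the rest", {
  rec <- data.frame(child_id = 1:4, sex = c("f", NA, "m", "f"),
                    age = c(10, 12, 14, 16), weight = 9, height = 80,
                    whz = c(0.3, 0.1, -7, 2))
  out <- filter_implausible(rec)
  expect_equal(out$records$child_id, c(1, 4))
  expect_equal(out$exclusions$reason[out$exclusions$child_id == 2],
               "missing_field")
  expect_equal(out$exclusions$reason[out$exclusions$child_id == 3],
               "implausible_z")
  # identity when everything is plausible
  ok <- filter_implausible(rec[c(1, 4), ])
  expect_equal(nrow(ok$exclusions), 0)
  expect_equal(ok$records, rec[c(1, 4), ])
  expect_error(filter_implausible(rec, bounds = c(2, -2)), "lo < hi")
})

test_that("cluster collapse matches a brute-force tally", {
  z <- c(-3, -2.5, 0, 1, 2.5)
  rec <- data.frame(cluster_id = 1, year = 2005, whz = z)
  obs <- collapse_clusters(rec)
  expect_equal(obs$N, 5)
  expect_equal(obs$C_w, 2)
  expect_equal(obs$N_cond, 3)
  expect_equal(obs$C_o, 1)

  # all-normal cluster
  rec2 <- data.frame(cluster_id = 1, year = 2005, whz = c(0, 1, -1))
  obs2 <- collapse_clusters(rec2)
  expect_equal(c(obs2$C_w, obs2$C_o, obs2$N_cond), c(0, 0, 3))

  # random record set vs independent per-child counting
  set.seed(7)
  rec3 <- data.frame(cluster_id = sample(1:6, 300, TRUE),
                     year = sample(2000:2002, 300, TRUE),
                     whz = rnorm(300, 0, 2))
  obs3 <- collapse_clusters(rec3)
  for (i in seq_len(nrow(obs3))) {
    sub <- rec3[rec3$cluster_id == obs3$cluster_id[i] &
                  rec3$year == obs3$year[i], ]
    expect_equal(obs3$N[i], nrow(sub))
    expect_equal(obs3$C_w[i], sum(sub$whz < -2))
    expect_equal(obs3$C_o[i], sum(sub$whz > 2))
    expect_equal(obs3$C_w[i] + obs3$C_o[i] +
                   sum(sub$whz >= -2 & sub$whz <= 2), obs3$N[i])
  }
  expect_equal(sum(obs3$N), nrow(rec3))

  # reversed conditioning swaps the stages
  obs_rev <- collapse_clusters(rec, conditioning = "overweight_first")
  expect_equal(obs_rev$C_w, 1)       # stage 1 counts overweight
  expect_equal(obs_rev$N_cond, 4)
  expect_equal(obs_rev$C_o, 2)       # wasted among non-overweight
})

test_that("classification of generator output reproduces planted categories", {
  w <- tiny_world()
  tr <- simulate_latent_truth(w, seed = 3)
  rec <- simulate_child_records(w, tr, n_clusters = 30,
                                seasonal_amplitude = 0, seed = 5)
  z <- compute_whz(rec, w$lms)
  expect_identical(classify_whz(z), classify_whz(rec$whz_base))
})

test_that("cluster observations round-trip through CSV", {
  rec <- data.frame(cluster_id = 1:2, year = 2005, whz = c(-3, 1))
  obs <- collapse_clusters(rec)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cluster_obs(obs, f)
  back <- read_cluster_obs(f)
  expect_equal(back$C_w, obs$C_w)
  expect_equal(back$N, obs$N)
})
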