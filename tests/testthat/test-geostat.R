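test_that("planted degenerate truth recovers the submodel weights", {
  # truth logit p equals the first of three covariates exactly; no GP, no
  # nugget in the generating process
  set.seed(11)
  n <- 800
  d <- data.frame(x = runif(n, 1, 10), y = runif(n, 1, 10),
                  year = 2000L, country = 1L, weight_obs = 1, N = 60)
  d$g1 <- rnorm(n, -1.5, 0.8)
  d$g2 <- rnorm(n, -1.5, 0.5)
  d$g3 <- rnorm(n, -1.5, 0.5)
  d$C <- rbinom(n, d$N, plogis(d$g1))
  fit <- fit_stage(cbind(C, N - C) ~ g1 + g2 + g3, d,
                   control = fit_control(include_gp = FALSE,
                                         include_country = FALSE),
                   stage = "w")
  cf <- coef(fit)
  b <- cf[c("beta_g1", "beta_g2", "beta_g3")]
  expect_equal(sum(b), 1, tolerance = 1e-12)   # exact by substitution
  expect_lt(abs(cf["beta0"]), 0.1)
  expect_gt(b["beta_g1"], 0.85)
  expect_lt(max(abs(b[2:3])), 0.12)
})

test_that("fitting is deterministic and returns a valid Laplace state", {
  sim <- simulate_stage_data(21, nx = 8, T = 3, n_obs = 100)
  ctl <- fit_control(include_country = FALSE, support_spacing = 3,
                     optim_maxit = 60)
  f1 <- fit_stage(cbind(C, N - C) ~ xc, sim$data, control = ctl)
  f2 <- fit_stage(cbind(C, N - C) ~ xc, sim$data, control = ctl)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$u_mode, f2$u_mode)
  expect_true(f1$converged)
  # curvature at the mode is symmetric positive definite
  S <- crossprod(f1$cholS)
  expect_equal(S, t(S), tolerance = 1e-10)
  expect_true(all(diag(f1$cholS) > 0))
  # kappa * delta = sqrt(8 nu) by construction
  expect_equal(f1$params$kappa * f1$params$delta, 4, tolerance = 1e-12)
})

test_that("boundary count configurations warn but proceed", {
  d <- data.frame(x = 1:10, y = 1, year = 2000L, country = 1L,
                  weight_obs = 1, N = 10, C = 0L, xc = -2)
  expect_warning(
    fit_stage(cbind(C, N - C) ~ xc, d,
              control = fit_control(include_gp = FALSE,
                                    include_country = FALSE)),
    "boundary")
})

test_that("posterior draws satisfy the continuation-ratio identity", {
  sim <- simulate_stage_data(31, nx = 8, T = 3, n_obs = 120)
  ctl <- fit_control(include_country = FALSE, support_spacing = 3,
                     optim_maxit = 60)
  fit_w <- fit_stage(cbind(C, N - C) ~ xc, sim$data, control = ctl,
                     stage = "wasting")
  fit_o <- fit_stage(cbind(C, N - C) ~ xc, sim$data, control = ctl,
                     stage = "overweight_cond")
  nd <- data.frame(x = sim$cells[, 1], y = sim$cells[, 2],
                   country = 1L, xc = sim$xc_cell)
  dr <- sample_posterior(fit_w, fit_o, nd, n_draws = 40, seed = 5)
  expect_lt(max(abs(dr$p_wasting + dr$p_over + dr$p_normal - 1)), 1e-12)
  expect_true(all(dr$p_wasting >= 0 & dr$p_wasting <= 1))
  expect_true(all(dr$p_normal >= 0 & dr$p_normal <= 1))
  expect_error(sample_posterior(fit_w, fit_o, nd, n_draws = 0), "at least 1")

  # a stage-2 fit forced to (numerically) zero conditional probability
  # makes overweight vanish and normal absorb the rest
  nd0 <- nd
  nd0$xc <- -30
  dr0 <- sample_posterior(fit_w, fit_o, nd, newdata_cond = nd0,
                          n_draws = 10, seed = 6)
  expect_lt(max(dr0$p_over), 1e-8)
  expect_equal(dr0$p_normal, 1 - dr0$p_wasting, tolerance = 1e-8)
})

test_that("prior sensitivity presets parameterize the documented grid", {
  p1 <- prior_preset("model1")
  expect_equal(p1$rho_mean, 4)
  expect_equal(p1$nugget_rate, 5e-5)
  p2 <- prior_preset("model2")
  expect_equal(p2$nugget_rate, 2)
  expect_equal(p2$country_rate, 5e-5)
  p3 <- prior_preset("model3")
  expect_equal(p3$country_rate, 2)
  p4 <- prior_preset("model4")
  expect_equal(c(p4$rho_mean, p4$rho_sd), c(0, 1.2))
  p5 <- prior_preset("model5")
  expect_equal(c(p5$rho_mean, p5$rho_sd), c(0, 2.58))
  expect_identical(prior_preset("main"), p1)
})

test_that("well-identified fits agree across prior presets", {
  sim <- simulate_stage_data(41, nx = 10, T = 3, n_obs = 250, N = 50)
  ctl <- fit_control(include_country = FALSE, support_spacing = 3,
                     optim_maxit = 80)
  nd <- data.frame(x = sim$cells[, 1], y = sim$cells[, 2], country = 1L,
                   xc = sim$xc_cell)
  f1 <- fit_stage(cbind(C, N - C) ~ xc, sim$data,
                  priors = prior_preset("model1"), control = ctl)
  f5 <- fit_stage(cbind(C, N - C) ~ xc, sim$data,
                  priors = prior_preset("model5"), control = ctl)
  p1 <- predict(f1, nd, n_draws = 60, seed = 2)
  p5 <- predict(f5, nd, n_draws = 60, seed = 2)
  expect_gt(cor(as.vector(p1), as.vector(p5)), 0.95)
})

test_that("logit-scale stacked covariates and model frame wiring line up", {
  p <- matrix(c(0.2, 0.5, 0.8, 0.4), 2, 2,
              dimnames = list(NULL, c("gam", "brt")))
  sc <- stacked_covariates(p)
  expect_equal(sc$gam, qlogis(c(0.2, 0.5)))
  expect_equal(sc$brt, qlogis(c(0.8, 0.4)))
})

test_that("weighted pseudo-likelihood scales information, not counts", {
  # one observation with weight 1 versus the same observation split into two
  # half-weight pseudo-points: identical fits
  base <- data.frame(x = c(2, 5, 8), y = c(2, 5, 8), year = 2000L,
                     country = 1L, weight_obs = 1, N = 40,
                     C = c(5, 10, 20), xc = -1)
  split <- rbind(base, base[1, ])
  split$weight_obs[c(1, 4)] <- 0.5
  ctl <- fit_control(include_gp = FALSE, include_nugget = FALSE,
                     include_country = FALSE)
  f_base <- fit_stage(cbind(C, N - C) ~ xc, base, control = ctl)
  f_split <- fit_stage(cbind(C, N - C) ~ xc, split, control = ctl)
  expect_equal(f_base$u_mode, f_split$u_mode, tolerance = 1e-8)
  expect_equal(f_base$log_marginal, f_split$log_marginal, tolerance = 1e-6)
})
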