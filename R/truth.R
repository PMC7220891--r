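#' Simulate the latent prevalence truth for a synthetic world
#'
#' Draws, for each of the two ordinal stages (wasting; overweight conditional
#' on not wasted), the linear predictor
#' `eta = beta0 + X beta + Z + eps_ctr` on the logit scale at every cell-year,
#' where `Z` is a zero-mean Gaussian process with separable Matern x AR1
#' covariance and the country effects are iid `N(0, gamma2_ctr)`. The
#' three-category prevalence surfaces are derived by the continuation-ratio
#' identity `p_over = (1 - p_wasting) * p_cond`.
#'
#' @param world a `toy_world`.
#' @param params named list with elements `wasting` and `overweight`, each a
#'   list with `beta0` (scalar), `beta` (coefficients on the world covariates)
#'   and `cov` (a [cov_params()]).
#' @param seed integer seed.
#'
#' @return a list of class `latent_truth` with per-stage components (`eta`,
#'   `Z`, `country_effects`, `beta0`, `beta`, `cov`) and prevalence arrays
#'   `p_wasting`, `p_over`, `p_normal` (cells x years).
#' @export
simulate_latent_truth <- function(world, params = default_truth_params(),
                                  seed = 1L) {
  stopifnot(inherits(world, "toy_world"))
  set.seed(as.integer(seed))
  coords <- as.matrix(world$cells[, c("x", "y")])
  T <- length(world$years)
  stages <- lapply(params, function(ps) {
    stopifnot(inherits(ps$cov, "cov_params"))
    if (length(ps$beta) != ncol(world$covariates)) {
      stop("`beta` length must match the number of world covariates",
           call. = FALSE)
    }
    if (ps$cov$omega2 > 0) {
      op <- spacetime_covariance(coords, T, ps$cov)
      Z <- st_draw(op)[, , 1]
    } else {
      Z <- matrix(0, nrow(coords), T)
    }
    ctr <- stats::rnorm(max(world$cells$country), 0, sqrt(ps$cov$gamma2_ctr))
    fixed <- ps$beta0 + drop(world$covariates %*% ps$beta)
    eta <- Z + fixed + ctr[world$cells$country]   # recycled down columns
    list(eta = eta, Z = Z, country_effects = ctr, beta0 = ps$beta0,
         beta = ps$beta, cov = ps$cov)
  })
  p_w <- stats::plogis(stages$wasting$eta)
  p_cond <- stats::plogis(stages$overweight$eta)
  p_o <- (1 - p_w) * p_cond
  structure(list(stages = stages, p_wasting = p_w, p_over = p_o,
                 p_normal = 1 - p_w - p_o, years = world$years,
                 seed = as.integer(seed)),
            class = "latent_truth")
}

#' Default latent-truth parameters
#'
#' Baseline intercepts put wasting near 8% and overweight near 5% prevalence
#' (the order of magnitude of recent LMIC-wide estimates). Most of the
#' logit-scale variance is carried by the smooth covariates (coefficient
#' variance about 1.5 against a residual GP variance of 0.3), reflecting the
#' modeling premise that the ensemble covariates are well correlated with the
#' outcome and the space-time GP only absorbs residual autocorrelation.
#'
#' @param omega2,delta,rho,gamma2_ctr shared GP and country-effect parameters.
#' @return parameter list suitable for [simulate_latent_truth()].
#' @export
default_truth_params <- function(omega2 = 0.3, delta = 3, rho = 0.9,
                                 gamma2_ctr = 0.1) {
  list(
    wasting = list(beta0 = -2.4, beta = c(1.0, -0.6, 0.4),
                   cov = cov_params(omega2, delta, rho,
                                    gamma2_ctr = gamma2_ctr)),
    overweight = list(beta0 = -2.9, beta = c(-0.8, 0.6, 0.5),
                      cov = cov_params(omega2, delta, rho,
                                       gamma2_ctr = gamma2_ctr))
  )
}
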