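#' Draw latent linear predictors for one stage at new locations
#'
#' Returns an `n_pred x T x n_draws` array of logit-scale draws. The latent
#' block (fixed effects, country effects, support-node GP values) is drawn
#' from the Laplace Gaussian at the hyperparameter mode (optionally with the
#' hyperparameters themselves drawn from a Gaussian at their mode), and the
#' GP is extended from the support nodes to the prediction points by exact
#' conditional (kriging) draws using the Kronecker structure: conditional
#' mean `(C_ps R_ss^-1 (x) I) z` and covariance
#' `omega2 (R_pp - C_ps R_ss^-1 C_sp) (x) R_time`. The nugget is excluded
#' unless `include_nugget = TRUE` (it models survey noise, not place-level
#' prevalence); when included, fresh nugget noise is added per prediction
#' point, year and draw.
#'
#' @param fit a `stage_fit`.
#' @param newdata prediction frame with the stage's covariate, coordinate and
#'   country columns.
#' @param n_draws number of draws.
#' @param seed integer seed.
#' @param include_nugget add observation-level nugget noise to each draw.
#' @param sample_theta draw hyperparameters from their Gaussian at the mode
#'   (requires the fit to carry a hyperparameter Hessian).
#' @return array of dimension `nrow(newdata)` x years x `n_draws`.
#' @export
sample_stage <- function(fit, newdata, n_draws = 1000, seed = 1L,
                         include_nugget = FALSE, sample_theta = FALSE) {
  stopifnot(inherits(fit, "stage_fit"))
  if (n_draws < 1) stop("`n_draws` must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  L <- fit$layout
  n_pred <- nrow(newdata)
  T <- L$T

  X <- stats::model.matrix(stats::delete.response(stats::terms(fit$formula)),
                           newdata)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (!identical(colnames(X), fit$covariate_names)) {
    stop("`newdata` does not carry the fitted covariate columns",
         call. = FALSE)
  }
  offset_p <- X[, L$H]
  Xf_p <- X[, -L$H, drop = FALSE] - offset_p

  ctr_idx <- if (length(fit$ctr_levels)) {
    match(newdata[[fit$country]], fit$ctr_levels)
  } else NULL

  use_theta_draws <- sample_theta && !is.null(fit$theta_hess)
  theta_chol <- if (use_theta_draws) {
    chol_jitter(solve(fit$theta_hess))
  } else NULL

  # at-mode kriging operators (recomputed per draw only under theta sampling)
  make_ops <- function(nat) {
    if (L$n_s == 0) return(NULL)
    Rss <- matern_matrix(fit$support, delta = nat$delta)
    Rps <- matern_matrix(as.matrix(newdata[, fit$coords]), fit$support,
                         delta = nat$delta)
    Rinv <- chol2inv(chol_jitter(Rss))
    B <- Rps %*% Rinv
    Schur <- matern_matrix(as.matrix(newdata[, fit$coords]),
                           delta = nat$delta) - B %*% t(Rps)
    Lt <- if (T > 1) chol_jitter(ar1_matrix(T, nat$rho)) else
      matrix(1, 1, 1)
    list(B = B, cholSchur = factor_psd(Schur), Lt = Lt)
  }
  ops <- make_ops(fit$params)

  eta <- array(NA_real_, c(n_pred, T, n_draws))
  for (k in seq_len(n_draws)) {
    nat <- fit$params
    ops_k <- ops
    if (use_theta_draws) {
      th <- fit$theta + drop(t(theta_chol) %*% stats::rnorm(length(fit$theta)))
      names(th) <- names(fit$theta)
      nat <- theta_natural(th, fit$control)
      ops_k <- make_ops(nat)
    }
    u <- fit$u_mode + backsolve(fit$cholS, stats::rnorm(L$d_r))
    beta0 <- u[1]
    b <- u[L$i_b]
    fixed <- beta0 + offset_p +
      if (L$H > 1) drop(Xf_p %*% b) else 0
    ctr <- numeric(n_pred)
    if (!is.null(ctr_idx)) {
      vals <- u[L$i_ctr]
      ctr <- ifelse(is.na(ctr_idx), NA_real_, vals[pmax(ctr_idx, 1L)])
      n_new <- sum(is.na(ctr_idx))
      if (n_new) {
        ctr[is.na(ctr_idx)] <- stats::rnorm(n_new, 0,
                                            sqrt(nat$gamma2_ctr))
      }
    }
    eta_k <- matrix(fixed + ctr, n_pred, T)
    if (L$n_s > 0) {
      z <- matrix(u[L$i_z], L$n_s, T)
      E <- matrix(stats::rnorm(n_pred * T), n_pred, T)
      Zp <- ops_k$B %*% z +
        sqrt(nat$omega2) * (t(ops_k$cholSchur) %*% E %*% ops_k$Lt)
      eta_k <- eta_k + Zp
    }
    if (include_nugget && fit$control$include_nugget) {
      eta_k <- eta_k + matrix(stats::rnorm(n_pred * T, 0,
                                           sqrt(nat$sigma2_nug)), n_pred, T)
    }
    eta[, , k] <- eta_k
  }
  dimnames(eta) <- list(NULL, fit$years, NULL)
  eta
}

#' Draw posterior three-category prevalence surfaces
#'
#' Combines the two stage fits into draw-level prevalence surfaces by the
#' continuation-ratio identity: per draw, cell and year,
#' `p_wasting = logit^-1(eta_w)`, `p_over = (1 - p_wasting) *
#' logit^-1(eta_cond)` and `p_normal = 1 - p_wasting - p_over`, so the three
#' categories sum to one by construction. The nugget is excluded from the
#' prevalence surfaces (see [fit_control()]); hyperparameters are plugged in
#' at their mode unless `sample_theta = TRUE` and the fits carry a
#' hyperparameter Hessian.
#'
#' @param fit_wasting `stage_fit` for the wasting stage.
#' @param fit_cond `stage_fit` for overweight conditional on not wasted.
#' @param newdata_wasting,newdata_cond prediction frames (one row per cell)
#'   carrying each stage's covariate columns plus the coordinate and country
#'   columns; both must have the same rows/cells.
#' @param n_draws number of posterior draws (default 1000).
#' @param seed integer seed.
#' @param sample_theta also propagate hyperparameter uncertainty.
#' @return object of class `posterior_draws`: arrays `p_wasting`, `p_over`,
#'   `p_normal` of dimension cells x years x draws, plus `years`, `n_draws`,
#'   `seed`.
#' @export
sample_posterior <- function(fit_wasting, fit_cond, newdata_wasting,
                             newdata_cond = newdata_wasting,
                             n_draws = 1000, seed = 1L,
                             sample_theta = FALSE) {
  if (nrow(newdata_wasting) != nrow(newdata_cond)) {
    stop("prediction frames of the two stages must align row-wise",
         call. = FALSE)
  }
  eta_w <- sample_stage(fit_wasting, newdata_wasting, n_draws, seed = seed,
                        sample_theta = sample_theta)
  eta_o <- sample_stage(fit_cond, newdata_cond, n_draws,
                        seed = as.integer(seed) + 1L,
                        sample_theta = sample_theta)
  p_w <- stats::plogis(eta_w)
  p_cond <- stats::plogis(eta_o)
  p_o <- (1 - p_w) * p_cond
  structure(list(p_wasting = p_w, p_over = p_o, p_normal = 1 - p_w - p_o,
                 years = fit_wasting$years, n_draws = n_draws,
                 seed = as.integer(seed)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$p_wasting)
  cat("Posterior prevalence draws:", d[1], "cells x", d[2], "years x", d[3],
      "draws\n")
  cat("  mean wasting", format(mean(x$p_wasting), digits = 3),
      "| mean overweight", format(mean(x$p_over), digits = 3), "\n")
  invisible(x)
}

#' Summarize posterior draws
#'
#' Per cell-year mean and central 95% uncertainty interval (2.5th and 97.5th
#' draw percentiles) for each category.
#' @param object a `posterior_draws`.
#' @param ... unused.
#' @return data frame with `cell`, `year`, `category`, `mean`, `lower`,
#'   `upper`.
#' @export
summary.posterior_draws <- function(object, ...) {
  cats <- c("p_wasting", "p_over", "p_normal")
  out <- do.call(rbind, lapply(cats, function(cat_nm) {
    a <- object[[cat_nm]]
    mu <- apply(a, c(1, 2), mean)
    lo <- apply(a, c(1, 2), function(v) {
      if (anyNA(v)) NA_real_ else stats::quantile(v, 0.025)
    })
    hi <- apply(a, c(1, 2), function(v) {
      if (anyNA(v)) NA_real_ else stats::quantile(v, 0.975)
    })
    data.frame(cell = rep(seq_len(nrow(mu)), ncol(mu)),
               year = rep(object$years, each = nrow(mu)),
               category = sub("^p_", "", cat_nm),
               mean = as.vector(mu), lower = as.vector(lo),
               upper = as.vector(hi))
  }))
  rownames(out) <- NULL
  out
}

#' Posterior-mean prevalence surfaces from a stage fit
#'
#' `predict` method: posterior mean of the stage probability at the rows of
#' `newdata` for each year, from `n_draws` Laplace draws.
#' @param object a `stage_fit`.
#' @param newdata prediction frame (covariates + coordinates + country).
#' @param n_draws number of draws used for the mean.
#' @param seed integer seed.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... unused.
#' @return matrix rows of `newdata` x years.
#' @export
predict.stage_fit <- function(object, newdata, n_draws = 200, seed = 1L,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- sample_stage(object, newdata, n_draws, seed = seed)
  out <- if (type == "response") {
    apply(stats::plogis(eta), c(1, 2), mean)
  } else {
    apply(eta, c(1, 2), mean)
  }
  colnames(out) <- object$years
  out
}

#' Simulate binomial observations from a fitted stage
#'
#' Posterior-predictive counts at the fitted observation locations: per
#' simulation, a latent draw (including fresh nugget noise, since observed
#' counts are survey-noisy) and a binomial draw of `C` given each
#' observation's `N`.
#' @param object a `stage_fit`.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return matrix observations x `nsim` of simulated counts.
#' @export
simulate.stage_fit <- function(object, nsim = 1, seed = 1L, ...) {
  nd <- object$data
  eta <- sample_stage(object, nd, nsim, seed = seed, include_nugget = TRUE)
  t_idx <- match(nd[[object$time]], object$years)
  out <- vapply(seq_len(nsim), function(k) {
    p <- stats::plogis(eta[cbind(seq_len(nrow(nd)), t_idx, k)])
    stats::rbinom(nrow(nd), object$N, p)
  }, integer(nrow(nd)))
  dimnames(out) <- NULL
  out
}

#' Plot a fitted prevalence surface
#'
#' Image map of the posterior-mean stage probability over the prediction
#' frame for one year.
#' @param x a `stage_fit`.
#' @param newdata prediction frame with coordinate columns.
#' @param year year to plot (default: last fitted year).
#' @param n_draws draws for the posterior mean.
#' @param ... passed to [graphics::image()].
#' @export
plot.stage_fit <- function(x, newdata, year = max(x$years), n_draws = 100,
                           ...) {
  p <- predict(x, newdata, n_draws = n_draws)
  ti <- match(year, x$years)
  xs <- sort(unique(newdata[[x$coords[1]]]))
  ys <- sort(unique(newdata[[x$coords[2]]]))
  m <- matrix(NA_real_, length(xs), length(ys))
  m[cbind(match(newdata[[x$coords[1]]], xs),
          match(newdata[[x$coords[2]]], ys))] <- p[, ti]
  graphics::image(xs, ys, m, xlab = x$coords[1], ylab = x$coords[2],
                  main = paste0(x$stage, " prevalence, ", year), ...)
  invisible(p)
}
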