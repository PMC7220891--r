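#' Control parameters for the geostatistical fit
#'
#' @param include_gp include the Matern x AR1 space-time Gaussian process.
#' @param include_nugget include the observation-level nugget effect.
#' @param include_country include iid country random effects.
#' @param support_spacing spacing (cell units) of the spatial support-node
#'   subgrid on which the GP is represented; observations attach to their
#'   nearest node and prediction uses exact conditional (kriging) draws.
#' @param max_newton maximum Newton iterations for the latent mode.
#' @param newton_tol convergence threshold on the gradient infinity norm.
#' @param optim_maxit maximum iterations of the hyperparameter optimizer.
#' @param optim_reltol relative tolerance of the hyperparameter optimizer.
#' @param fixed named list fixing all hyperparameters on the natural scale
#'   (`omega2`, `delta`, `rho`, `sigma2_nug`, `gamma2_ctr`); when supplied the
#'   hyperparameter optimization is skipped entirely.
#' @param theta_hessian also compute the curvature of the hyperparameter
#'   posterior at the mode (needed for hyperparameter sampling at prediction
#'   time).
#' @param verbose print optimizer progress.
#' @return a list of class `fit_control`.
#' @export
fit_control <- function(include_gp = TRUE, include_nugget = TRUE,
                        include_country = TRUE, support_spacing = 3,
                        max_newton = 50, newton_tol = 1e-6,
                        optim_maxit = 200, optim_reltol = 1e-7,
                        fixed = NULL, theta_hessian = FALSE,
                        verbose = FALSE) {
  structure(list(include_gp = include_gp, include_nugget = include_nugget,
                 include_country = include_country,
                 support_spacing = support_spacing, max_newton = max_newton,
                 newton_tol = newton_tol, optim_maxit = optim_maxit,
                 optim_reltol = optim_reltol, fixed = fixed,
                 theta_hessian = theta_hessian, verbose = verbose),
            class = "fit_control")
}

# Build the support-node subgrid covering the observation extent.
make_support_nodes <- function(x, y, spacing) {
  gx <- seq(floor(min(x)), ceiling(max(x)), by = spacing)
  gy <- seq(floor(min(y)), ceiling(max(y)), by = spacing)
  as.matrix(expand.grid(x = gx, y = gy))
}

# Index of the nearest support node for each point.
nearest_node <- function(x, y, nodes) {
  vapply(seq_along(x), function(i) {
    which.min((nodes[, 1] - x[i])^2 + (nodes[, 2] - y[i])^2)
  }, integer(1))
}

# --- theta transforms ------------------------------------------------------
# Internal hyperparameter vector (subset depending on control flags):
#   log(omega2), log(kappa), fisher(rho), log(tau_nug), log(tau_ctr)
fisher <- function(rho) log((1 + rho) / (1 - rho))
inv_fisher <- function(z) (exp(z) - 1) / (exp(z) + 1)

theta_names <- function(ctl, n_years) {
  nm <- character(0)
  if (ctl$include_gp) {
    nm <- c(nm, "log_omega2", "log_kappa")
    if (n_years > 1) nm <- c(nm, "fisher_rho")
  }
  if (ctl$include_nugget) nm <- c(nm, "log_tau_nug")
  if (ctl$include_country) nm <- c(nm, "log_tau_ctr")
  nm
}

theta_natural <- function(theta, ctl, nu = 2) {
  g <- function(nm, default) if (nm %in% names(theta)) unname(theta[nm])
                             else default
  kappa <- exp(g("log_kappa", NA))
  list(omega2 = exp(g("log_omega2", -Inf)),
       kappa = kappa, delta = sqrt(8 * nu) / kappa,
       rho = inv_fisher(g("fisher_rho", 0)),
       sigma2_nug = 1 / exp(g("log_tau_nug", Inf)),
       gamma2_ctr = 1 / exp(g("log_tau_ctr", Inf)))
}

# log prior of theta on the internal (transformed) scale, Jacobians included.
theta_logprior <- function(theta, ctl, priors) {
  lp <- 0
  if ("log_omega2" %in% names(theta)) {
    lp <- lp + stats::dnorm(theta["log_omega2"], priors$theta1_mean,
                            priors$theta1_sd, log = TRUE)
  }
  if ("log_kappa" %in% names(theta)) {
    lp <- lp + stats::dnorm(theta["log_kappa"], priors$theta2_mean,
                            priors$theta2_sd, log = TRUE)
  }
  if ("fisher_rho" %in% names(theta)) {
    lp <- lp + stats::dnorm(theta["fisher_rho"], priors$rho_mean,
                            priors$rho_sd, log = TRUE)
  }
  if ("log_tau_nug" %in% names(theta)) {
    tau <- exp(theta["log_tau_nug"])
    lp <- lp + stats::dgamma(tau, priors$nugget_shape,
                             rate = priors$nugget_rate, log = TRUE) +
      theta["log_tau_nug"]
  }
  if ("log_tau_ctr" %in% names(theta)) {
    tau <- exp(theta["log_tau_ctr"])
    lp <- lp + stats::dgamma(tau, priors$country_shape,
                             rate = priors$country_rate, log = TRUE) +
      theta["log_tau_ctr"]
  }
  unname(lp)
}

#' Fit one stage of the continuation-ratio geostatistical model
#'
#' Fits the latent-Gaussian binomial model
#' `logit(p_{i,t}) = beta0 + X_{i,t} beta + Z_{i,t} + eps_ctr(i) + eps_{i,t}`
#' with `sum(beta) = 1`, a Matern (nu = 2) x AR1 space-time Gaussian process
#' `Z` on a support-node subgrid, iid country effects and an observation-level
#' nugget, to weighted cluster-level binomial counts. The sum-to-one
#' constraint is enforced by substituting `beta_H = 1 - sum(beta_h, h < H)`;
#' the prior on the free coefficients is the exact conditional of the iid
#' normal prior given the constraint. The latent block is integrated by a
#' Laplace (Newton-optimized Gaussian) approximation; the hyperparameters
#' maximize the Laplace-approximated marginal posterior. The nugget dimension
#' is eliminated analytically from every Newton solve via its Schur
#' complement, so the factorized dimension is fixed effects + countries +
#' support nodes x years.
#'
#' @param formula model formula, e.g.
#'   `cbind(C_w, N - C_w) ~ gam + brt + lasso`, where the right-hand side
#'   names the H stacked-submodel covariate columns (conventionally on the
#'   logit scale, see [stacked_covariates()]). No intercept term should be
#'   given; the intercept `beta0` is always present.
#' @param data data frame with the response counts, covariates, coordinates,
#'   year, country and observation weights.
#' @param coords names of the coordinate columns.
#' @param time name of the year column; years are treated as consecutive
#'   integers spanning `range(data[[time]])`.
#' @param country name of the country column.
#' @param weights name of the observation-weight column (1 for ordinary
#'   clusters, resampling weights for polygon pseudo-points); the binomial
#'   log-likelihood term of each row is multiplied by its weight.
#' @param support optional matrix of support-node coordinates; by default a
#'   subgrid with spacing `control$support_spacing` over the observation
#'   extent.
#' @param priors a [prior_config()].
#' @param control a [fit_control()].
#' @param seed integer seed (recorded; the fit itself is deterministic).
#' @param stage label for printing (e.g. `"wasting"`).
#' @return object of class `stage_fit`; see [coef.stage_fit()],
#'   [sample_posterior()].
#' @export
fit_stage <- function(formula, data, coords = c("x", "y"), time = "year",
                      country = "country", weights = "weight_obs",
                      support = NULL, priors = prior_config(),
                      control = fit_control(), seed = 1L,
                      stage = "stage") {
  stopifnot(inherits(priors, "prior_config"), inherits(control, "fit_control"))
  mf <- stats::model.frame(formula, data)
  Y <- stats::model.response(mf)
  if (is.null(dim(Y)) || ncol(Y) != 2) {
    stop("response must be a two-column matrix cbind(successes, failures)",
         call. = FALSE)
  }
  C <- Y[, 1]; N <- rowSums(Y)
  X <- stats::model.matrix(formula, data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  H <- ncol(X)
  if (H < 1) stop("at least one covariate is required", call. = FALSE)
  w <- if (weights %in% names(data)) data[[weights]] else rep(1, nrow(data))
  if (any(w <= 0)) stop("observation weights must be positive", call. = FALSE)
  if (all(C == 0) || all(C == N)) {
    warning("all counts are at the boundary (all zero or all N); ",
            "the fit proceeds but is weakly identified")
  }

  # constraint substitution: X beta = X_H + sum_{h<H} (X_h - X_H) beta_h
  offset <- X[, H]
  Xf <- X[, -H, drop = FALSE] - offset
  m_beta <- if (is.null(priors$beta_mean)) 1 / H else priors$beta_mean

  years <- seq(min(data[[time]]), max(data[[time]]))
  T <- length(years)
  t_idx <- match(data[[time]], years)

  ctr_levels <- if (control$include_country) sort(unique(data[[country]]))
                else integer(0)
  n_ctr <- length(ctr_levels)
  ctr_idx <- if (n_ctr) match(data[[country]], ctr_levels) else NULL

  if (control$include_gp) {
    if (is.null(support)) {
      support <- make_support_nodes(data[[coords[1]]], data[[coords[2]]],
                                    control$support_spacing)
    }
    support <- as.matrix(support)
    n_s <- nrow(support)
    node <- nearest_node(data[[coords[1]]], data[[coords[2]]], support)
    z_col_of_obs <- (t_idx - 1L) * n_s + node
  } else {
    support <- matrix(numeric(0), 0, 2)
    n_s <- 0
    z_col_of_obs <- NULL
  }
  n_z <- n_s * T
  n_obs <- length(C)

  # latent layout (nugget handled separately): [beta0 | b_free | ctr | z]
  d_r <- 1L + (H - 1L) + n_ctr + n_z
  i_b <- if (H > 1) 1L + seq_len(H - 1L) else integer(0)
  i_ctr <- if (n_ctr) 1L + (H - 1L) + seq_len(n_ctr) else integer(0)
  i_z <- if (n_z) 1L + (H - 1L) + n_ctr + seq_len(n_z) else integer(0)

  A <- matrix(0, n_obs, d_r)
  A[, 1] <- 1
  if (H > 1) A[, i_b] <- Xf
  if (n_ctr) A[cbind(seq_len(n_obs), i_ctr[ctr_idx])] <- 1
  if (n_z) A[cbind(seq_len(n_obs), i_z[z_col_of_obs])] <- 1

  m_r <- numeric(d_r)
  m_r[1] <- priors$beta0_mean
  if (H > 1) m_r[i_b] <- m_beta

  # theta-independent prior precision pieces for beta0 and the constrained
  # free coefficients: Sigma_b = beta_sd^2 (I - J/H) => inverse (I + J)/sd^2
  Q_fixed <- matrix(0, d_r, d_r)
  Q_fixed[1, 1] <- 1 / priors$beta0_sd^2
  logdet_Q_fixed <- -2 * log(priors$beta0_sd)
  if (H > 1) {
    m <- H - 1L
    Q_fixed[i_b, i_b] <- (diag(m) + matrix(1, m, m)) / priors$beta_sd^2
    logdet_Q_fixed <- logdet_Q_fixed + log(H) - 2 * m * log(priors$beta_sd)
  }

  loglik <- function(eta) {
    p <- stats::plogis(eta)
    sum(w * (C * log(p) + (N - C) * log1p(-p)))
  }

  # Laplace machinery at one theta value; warm-started latent mode lives in
  # `state`.
  state <- new.env(parent = emptyenv())
  state$u_r <- m_r
  state$e <- numeric(n_obs)

  laplace_at <- function(theta) {
    nat <- theta_natural(theta, control)
    Q_r <- Q_fixed
    logdet_Q <- logdet_Q_fixed
    if (n_ctr) {
      tau_c <- 1 / nat$gamma2_ctr
      ii <- cbind(i_ctr, i_ctr)
      Q_r[ii] <- Q_r[ii] + tau_c
      logdet_Q <- logdet_Q + n_ctr * log(tau_c)
    }
    if (n_z) {
      cp <- cov_params(omega2 = nat$omega2, delta = nat$delta,
                       rho = if (T > 1) nat$rho else 0)
      op <- spacetime_covariance(support, T, cp)
      Q_r[i_z, i_z] <- Q_r[i_z, i_z] + st_precision(op)
      logdet_Q <- logdet_Q - logdet.st_cov(op)
    }
    has_nug <- control$include_nugget
    tau_e <- if (has_nug) 1 / nat$sigma2_nug else Inf
    if (has_nug) logdet_Q <- logdet_Q + n_obs * log(tau_e)

    u_r <- state$u_r
    e <- if (has_nug) state$e else numeric(n_obs)
    eta_of <- function(u_r, e) drop(A %*% u_r) + e + offset
    fval <- function(u_r, e) {
      du <- u_r - m_r
      v <- loglik(eta_of(u_r, e)) - 0.5 * drop(crossprod(du, Q_r %*% du))
      if (has_nug) v <- v - 0.5 * tau_e * sum(e^2)
      v
    }
    f_cur <- fval(u_r, e)
    if (!is.finite(f_cur)) { u_r <- m_r; e <- numeric(n_obs)
                             f_cur <- fval(u_r, e) }
    converged <- FALSE
    cholS <- NULL
    W <- NULL
    for (it in seq_len(control$max_newton)) {
      eta <- eta_of(u_r, e)
      p <- stats::plogis(eta)
      gvec <- w * (C - N * p)
      W <- pmax(w * N * p * (1 - p), 1e-12)
      g_r <- drop(crossprod(A, gvec)) - drop(Q_r %*% (u_r - m_r))
      if (has_nug) {
        g_e <- gvec - tau_e * e
        cvec <- W * tau_e / (tau_e + W)
      } else {
        g_e <- numeric(0)
        cvec <- W
      }
      gnorm <- max(abs(c(g_r, g_e)))
      S <- Q_r + crossprod(A * sqrt(cvec))
      cholS <- chol_jitter(S)
      if (gnorm < control$newton_tol) { converged <- TRUE; break }
      if (has_nug) {
        rhs <- g_r - drop(crossprod(A, W * g_e / (tau_e + W)))
        x_r <- backsolve(cholS, backsolve(cholS, rhs, transpose = TRUE))
        x_e <- (g_e - W * drop(A %*% x_r)) / (tau_e + W)
      } else {
        x_r <- backsolve(cholS, backsolve(cholS,
                                          g_r, transpose = TRUE))
        x_e <- numeric(n_obs)
      }
      step <- 1
      repeat {
        u_new <- u_r + step * x_r
        e_new <- if (has_nug) e + step * x_e else e
        f_new <- fval(u_new, e_new)
        if (is.finite(f_new) && f_new >= f_cur - 1e-10) break
        step <- step / 2
        if (step < 1e-8) { u_new <- u_r; e_new <- e; f_new <- f_cur; break }
      }
      u_r <- u_new; e <- e_new; f_cur <- f_new
    }
    state$u_r <- u_r
    state$e <- e
    logdet_P <- 2 * sum(log(diag(cholS))) +
      if (has_nug) sum(log(tau_e + W)) else 0
    log_marg <- f_cur + 0.5 * logdet_Q - 0.5 * logdet_P
    list(log_marg = log_marg, u_r = u_r, e = e, cholS = cholS, W = W,
         converged = converged, Q_r = Q_r, nat = nat,
         logdet_Q = logdet_Q, logdet_P = logdet_P, f_mode = f_cur)
  }

  nm <- theta_names(control, T)
  if (!is.null(control$fixed)) {
    fx <- control$fixed
    theta_hat <- stats::setNames(numeric(length(nm)), nm)
    if ("log_omega2" %in% nm) theta_hat["log_omega2"] <- log(fx$omega2)
    if ("log_kappa" %in% nm) theta_hat["log_kappa"] <- log(sqrt(8 * 2) /
                                                             fx$delta)
    if ("fisher_rho" %in% nm) theta_hat["fisher_rho"] <- fisher(fx$rho)
    if ("log_tau_nug" %in% nm) theta_hat["log_tau_nug"] <- -log(fx$sigma2_nug)
    if ("log_tau_ctr" %in% nm) theta_hat["log_tau_ctr"] <- -log(fx$gamma2_ctr)
    opt <- NULL
  } else if (length(nm) == 0) {
    theta_hat <- stats::setNames(numeric(0), character(0))
    opt <- NULL
  } else {
    # moment-flavoured initial values from empirical-logit residuals
    r <- stats::qlogis(clamp_prob((C + 0.5) / (N + 1))) - offset
    v0 <- max(stats::var(r), 0.05)
    span <- max(diff(range(data[[coords[1]]])),
                diff(range(data[[coords[2]]])), 2)
    init <- stats::setNames(numeric(length(nm)), nm)
    if ("log_omega2" %in% nm) init["log_omega2"] <- log(0.5 * v0)
    if ("log_kappa" %in% nm) init["log_kappa"] <- log(4 / (span / 4))
    if ("fisher_rho" %in% nm) init["fisher_rho"] <- 2
    if ("log_tau_nug" %in% nm) init["log_tau_nug"] <- -log(0.2 * v0)
    if ("log_tau_ctr" %in% nm) init["log_tau_ctr"] <- -log(0.5 * v0)
    negpost <- function(th) {
      th <- stats::setNames(th, nm)
      # extreme proposals (e.g. a range far beyond the node spacing) can make
      # the node correlation numerically singular; treat them as -Inf posterior
      lp <- tryCatch(
        laplace_at(th)$log_marg + theta_logprior(th, control, priors),
        error = function(e) -1e10)
      if (!is.finite(lp)) lp <- -1e10
      if (control$verbose) {
        cat(sprintf("  theta = [%s]  logpost = %.4f\n",
                    paste(sprintf("%.3f", th), collapse = ", "), lp))
      }
      -lp
    }
    opt <- if (length(nm) == 1) {
      stats::optim(init, negpost, method = "Brent",
                   lower = init - 12, upper = init + 12)
    } else {
      stats::optim(init, negpost, method = "Nelder-Mead",
                   control = list(maxit = control$optim_maxit,
                                  reltol = control$optim_reltol))
    }
    theta_hat <- stats::setNames(opt$par, nm)
  }

  final <- laplace_at(theta_hat)
  if (!final$converged) {
    warning("inner Newton iteration did not reach tolerance ",
            control$newton_tol, " within ", control$max_newton,
            " iterations")
  }
  theta_hess <- NULL
  if (control$theta_hessian && length(nm) > 0 && is.null(control$fixed)) {
    negpost2 <- function(th) {
      th <- stats::setNames(th, nm)
      -(laplace_at(th)$log_marg + theta_logprior(th, control, priors))
    }
    theta_hess <- stats::optimHess(theta_hat, negpost2)
    final <- laplace_at(theta_hat)
  }

  structure(list(stage = stage, theta = theta_hat, params = final$nat,
                 log_marginal = final$log_marg,
                 theta_logpost = final$log_marg +
                   if (length(theta_hat)) theta_logprior(theta_hat, control,
                                                         priors) else 0,
                 u_mode = final$u_r, e_mode = final$e, cholS = final$cholS,
                 W = final$W, Q_r = final$Q_r, theta_hess = theta_hess,
                 converged = final$converged, opt = opt,
                 layout = list(H = H, d_r = d_r, i_b = i_b, i_ctr = i_ctr,
                               i_z = i_z, n_s = n_s, T = T, n_obs = n_obs),
                 support = support, years = years,
                 ctr_levels = ctr_levels,
                 covariate_names = colnames(X),
                 formula = formula, coords = coords, time = time,
                 country = country,
                 data = data, A = A, offset = offset, C = C, N = N, w = w,
                 m_r = m_r, priors = priors, control = control,
                 internals = list(loglik = loglik, laplace_at = laplace_at),
                 seed = as.integer(seed)),
            class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat("Continuation-ratio geostatistical stage fit (", x$stage, ")\n",
      sep = "")
  cat("  ", x$layout$n_obs, "observations,", x$layout$n_s, "support nodes x",
      x$layout$T, "years,", length(x$ctr_levels), "countries\n")
  cf <- coef(x)
  cat("  beta0 =", format(cf["beta0"], digits = 3), "; beta = (",
      paste(format(cf[grep("^beta_", names(cf))], digits = 3),
            collapse = ", "), ") [sum-to-one]\n")
  p <- x$params
  if (x$control$include_gp) {
    cat("  GP: omega2 =", format(p$omega2, digits = 3), ", delta =",
        format(p$delta, digits = 3), ", rho =", format(p$rho, digits = 3),
        "\n")
  }
  if (x$control$include_nugget) {
    cat("  nugget sigma2 =", format(p$sigma2_nug, digits = 3), "\n")
  }
  if (x$control$include_country) {
    cat("  country gamma2 =", format(p$gamma2_ctr, digits = 3), "\n")
  }
  cat("  Laplace log marginal likelihood:",
      format(x$log_marginal, digits = 6), "\n")
  invisible(x)
}

#' Coefficients of a stage fit
#'
#' Posterior modes of the intercept and stacking coefficients (with the
#' constrained `beta_H` reconstructed so the returned betas sum to one
#' exactly) followed by the hyperparameter estimates.
#' @param object a `stage_fit`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.stage_fit <- function(object, ...) {
  L <- object$layout
  b_free <- object$u_mode[L$i_b]
  beta <- c(b_free, 1 - sum(b_free))
  names(beta) <- paste0("beta_", object$covariate_names)
  out <- c(beta0 = object$u_mode[1], beta)
  p <- object$params
  if (object$control$include_gp) {
    out <- c(out, omega2 = p$omega2, delta = p$delta, rho = p$rho)
  }
  if (object$control$include_nugget) out <- c(out, sigma2_nug = p$sigma2_nug)
  if (object$control$include_country) out <- c(out, gamma2_ctr = p$gamma2_ctr)
  out
}

#' @export
logLik.stage_fit <- function(object, ...) {
  structure(object$log_marginal, df = length(object$theta),
            class = "logLik")
}

#' @export
summary.stage_fit <- function(object, ...) {
  L <- object$layout
  Sigma_r <- chol2inv(object$cholS)
  sds <- sqrt(diag(Sigma_r))
  cf <- data.frame(estimate = c(object$u_mode[1], object$u_mode[L$i_b]),
                   sd = c(sds[1], sds[L$i_b]),
                   row.names = c("beta0",
                                 if (L$H > 1)
                                   paste0("beta_",
                                          object$covariate_names[-L$H])))
  out <- list(stage = object$stage, coefficients = cf,
              hyperparameters = object$params,
              log_marginal = object$log_marginal,
              converged = object$converged, layout = L)
  class(out) <- "summary.stage_fit"
  out
}

#' @export
print.summary.stage_fit <- function(x, ...) {
  cat("Stage:", x$stage, "\n\nLatent fixed effects (posterior mode, sd):\n")
  print(x$coefficients, digits = 4)
  cat("\nHyperparameters at the marginal-posterior mode:\n")
  hp <- x$hyperparameters
  print(unlist(hp[c("omega2", "delta", "rho", "sigma2_nug", "gamma2_ctr")]),
        digits = 4)
  cat("\nLaplace log marginal likelihood:", format(x$log_marginal,
                                                   digits = 6), "\n")
  invisible(x)
}

#' Pearson residuals of a stage fit
#'
#' Residuals `(C - N p) / sqrt(N p (1 - p))` at the latent posterior mode
#' (including the fitted nugget mode).
#' @param object a `stage_fit`.
#' @param ... unused.
#' @return numeric vector, one per observation.
#' @export
residuals.stage_fit <- function(object, ...) {
  eta <- drop(object$A %*% object$u_mode) + object$e_mode + object$offset
  p <- stats::plogis(eta)
  (object$C - object$N * p) / sqrt(pmax(object$N * p * (1 - p), 1e-12))
}

#' Fitted stage prevalences at the observation locations
#' @param object a `stage_fit`.
#' @param ... unused.
#' @return vector of fitted probabilities (nugget mode included).
#' @export
fitted.stage_fit <- function(object, ...) {
  stats::plogis(drop(object$A %*% object$u_mode) + object$e_mode +
                  object$offset)
}

#' Logit-scale stacked covariates
#'
#' Convenience accessor turning submodel probability predictions into the
#' logit-scale covariate columns the geostatistical stage expects, so that the
#' sum-to-one coefficients weight the submodels on the link scale.
#'
#' @param p matrix or data frame of submodel probabilities.
#' @return data frame of logits, same column names.
#' @export
stacked_covariates <- function(p) {
  as.data.frame(lapply(as.data.frame(p), function(col) {
    stats::qlogis(clamp_prob(col))
  }))
}
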