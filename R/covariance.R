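#' Space-time covariance parameters
#'
#' Parameters of the separable Matern (space) x AR1 (time) Gaussian-process
#' covariance plus the unstructured variance components. The Matern smoothness
#' is fixed at `nu = 2` and the scaling parameter is derived as
#' `kappa = sqrt(8 * nu) / delta`, so that the correlation at distance `delta`
#' has dropped to roughly 0.1 (the conventional "range" reading).
#'
#' @param omega2 marginal variance of the Gaussian process (> 0, or 0 for a
#'   degenerate process that is identically zero).
#' @param delta spatial range in cell units (> 0).
#' @param rho temporal AR1 correlation, strictly inside (-1, 1).
#' @param sigma2_nug nugget (observation-level) variance, >= 0.
#' @param gamma2_ctr country random-effect variance, >= 0.
#' @param nu Matern smoothness; fixed at 2 in this model family.
#'
#' @return a list of class `cov_params` with derived `kappa`.
#' @export
cov_params <- function(omega2 = 1, delta = 3, rho = 0.9, sigma2_nug = 0,
                       gamma2_ctr = 0, nu = 2) {
  if (omega2 < 0) stop("`omega2` must be nonnegative", call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  if (sigma2_nug < 0 || gamma2_ctr < 0) {
    stop("variances must be nonnegative", call. = FALSE)
  }
  structure(list(omega2 = omega2, delta = delta, nu = nu,
                 kappa = sqrt(8 * nu) / delta, rho = rho,
                 sigma2_nug = sigma2_nug, gamma2_ctr = gamma2_ctr),
            class = "cov_params")
}

#' Matern correlation function
#'
#' `r(D) = (kappa D)^nu K_nu(kappa D) / (Gamma(nu) 2^(nu - 1))` with
#' `kappa = sqrt(8 nu) / delta`. The removable singularity at `D = 0` is
#' handled explicitly (`r(0) = 1`). With the default `nu = 2`, the correlation
#' at `D = delta` is about 0.139, consistent with reading `delta` as the
#' distance where correlation approaches 0.1.
#'
#' @param D Euclidean distance(s), >= 0.
#' @param delta range parameter (> 0).
#' @param nu smoothness (> 0); default 2.
#' @return correlation value(s) in (0, 1].
#' @export
matern_correlation <- function(D, delta, nu = 2) {
  if (any(D < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  kappa <- sqrt(8 * nu) / delta
  kd <- kappa * D
  out <- numeric(length(kd))
  zero <- kd < .Machine$double.eps^0.5
  out[zero] <- 1
  if (any(!zero)) {
    x <- kd[!zero]
    # evaluate on log scale: besselK underflows for large kd
    out[!zero] <- exp(nu * log(x) + log(besselK(x, nu, expon.scaled = TRUE)) -
                        x - lgamma(nu) - (nu - 1) * log(2))
  }
  if (length(dim(D))) dim(out) <- dim(D)
  out
}

# Spatial Matern correlation matrix over point sets (rows of coords).
matern_matrix <- function(coords1, coords2 = coords1, delta, nu = 2) {
  d <- sqrt(outer(coords1[, 1], coords2[, 1], "-")^2 +
              outer(coords1[, 2], coords2[, 2], "-")^2)
  matern_correlation(d, delta, nu)
}

# AR1 correlation matrix over T consecutive time points.
ar1_matrix <- function(T, rho) {
  rho^abs(outer(seq_len(T), seq_len(T), "-"))
}

# Tridiagonal precision of a unit-variance AR1 over T points (analytic inverse
# of ar1_matrix). For T = 1 this is the 1x1 identity.
ar1_precision <- function(T, rho) {
  if (T == 1) return(matrix(1, 1, 1))
  Q <- diag(c(1, rep(1 + rho^2, T - 2), 1))
  for (j in seq_len(T - 1)) {
    Q[j, j + 1] <- Q[j + 1, j] <- -rho
  }
  Q / (1 - rho^2)
}

# Cholesky with escalating diagonal jitter; errors with guidance if the
# matrix stays indefinite.
chol_jitter <- function(M, max_tries = 6) {
  jit <- 0
  for (i in seq_len(max_tries)) {
    L <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) 1e-10 * mean(diag(M)) else jit * 100
  }
  stop("covariance matrix is not positive definite even after jitter; ",
       "check the range parameter against the node spacing", call. = FALSE)
}

# Square-root factor R (with crossprod(R) = M) of a possibly rank-deficient
# covariance matrix: Cholesky with jitter when possible, otherwise an
# eigenvalue-clipped factor. Only for drawing correlated noise -- not for
# solving systems (R need not be triangular on the fallback path).
factor_psd <- function(M) {
  tryCatch(chol_jitter(M), error = function(e) {
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
  })
}

#' Separable space-time covariance operator
#'
#' Represents `Sigma = omega2 * R_space (x) R_time` (Kronecker product) over a
#' set of spatial nodes and consecutive years through its factor Cholesky
#' decompositions; the full `(n T) x (n T)` matrix is never materialized.
#' Column-major layout: the latent vector stacks nodes within year 1, then
#' year 2, etc. (space index varies fastest).
#'
#' @param coords matrix of node coordinates (n x 2).
#' @param n_years number of consecutive years T.
#' @param params a [cov_params()].
#' @return a list of class `st_cov` with the spatial/temporal correlation
#'   factors, their inverses' log-determinants, and dimensions.
#' @export
spacetime_covariance <- function(coords, n_years, params) {
  stopifnot(inherits(params, "cov_params"))
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1 || n_years < 1) stop("need >= 1 node and >= 1 year", call. = FALSE)
  Rs <- matern_matrix(coords, delta = params$delta, nu = params$nu)
  Ls <- chol_jitter(Rs)                      # upper-triangular: Rs = t(Ls) Ls
  Qt <- ar1_precision(n_years, params$rho)
  logdet_Rs <- 2 * sum(log(diag(Ls)))
  logdet_Rt <- if (n_years > 1) (n_years - 1) * log(1 - params$rho^2) else 0
  structure(list(coords = coords, n_space = n, n_years = n_years,
                 params = params, R_space = Rs, chol_space = Ls,
                 Q_time = Qt, logdet_R_space = logdet_Rs,
                 logdet_R_time = logdet_Rt),
            class = "st_cov")
}

# log|Sigma| via Kronecker identities.
logdet.st_cov <- function(op) {
  nT <- op$n_space * op$n_years
  nT * log(op$params$omega2) +
    op$n_years * op$logdet_R_space + op$n_space * op$logdet_R_time
}

# Precision matrix (dense) of the stacked field; used as a prior block in the
# Laplace fit. Q = (1/omega2) * Rs^{-1} (x) Qt  with space varying fastest.
st_precision <- function(op) {
  Qs <- chol2inv(op$chol_space)
  kronecker(op$Q_time, Qs) / op$params$omega2
}

# Draw one realization of the stacked field as an n_space x n_years matrix.
st_draw <- function(op, n_draws = 1) {
  Lt <- chol_jitter(ar1_matrix(op$n_years, op$params$rho))
  sapply(seq_len(n_draws), function(i) {
    E <- matrix(stats::rnorm(op$n_space * op$n_years), op$n_space)
    sqrt(op$params$omega2) * (t(op$chol_space) %*% E %*% Lt)
  }, simplify = "array")
}
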