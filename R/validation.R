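#' Spatially stratified fold assignment by admin1 blocks
#'
#' Every admin1 unit is placed wholly in one fold, so held-out observations
#' are spatially separated from the training data. Units are allocated
#' greedily: in decreasing order of observation count (random tie-breaking
#' under the seed), each unit joins the currently smallest fold.
#'
#' @param admin1 admin1 unit id per observation.
#' @param k number of folds (default 5); requires at least `k` distinct
#'   units.
#' @param seed integer seed.
#' @return integer fold label per observation.
#' @export
spatial_folds <- function(admin1, k = 5, seed = 1L) {
  units <- unique(admin1)
  if (length(units) < k) {
    stop("need at least ", k, " admin1 units for ", k, " spatial folds",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  counts <- table(admin1)[as.character(units)]
  ord <- order(counts + stats::runif(length(counts)), decreasing = TRUE)
  fold_of_unit <- stats::setNames(integer(length(units)),
                                  as.character(units))
  fold_sizes <- numeric(k)
  for (u in units[ord]) {
    f <- which.min(fold_sizes)
    fold_of_unit[as.character(u)] <- f
    fold_sizes[f] <- fold_sizes[f] + counts[as.character(u)]
  }
  unname(fold_of_unit[as.character(admin1)])
}

#' Out-of-sample validation metrics
#'
#' The four metrics computed on held-out observations: bias (mean error of
#' the posterior-mean prevalence against observed frequencies `C/N`),
#' root-mean-square error, 95% data coverage (fraction of observed counts
#' inside the central 95% interval of draw-level `Binomial(N, p_draw)`
#' predictive counts — the predictive draws should include the nugget and
#' binomial sampling layers since observed counts are survey-noisy), and
#' Pearson correlation. Coverage intervals for the discrete counts are the
#' smallest central set with at least 95% mass (inclusive, conservative
#' ties).
#'
#' @param C,N observed counts and sample sizes of the held-out clusters.
#' @param p_draws held-out observations x draws matrix of predictive
#'   prevalence draws at the cluster locations/years.
#' @return one-row data frame: `n`, `bias`, `rmse`, `coverage`, `correlation`
#'   (`NA` if either vector has zero variance).
#' @export
holdout_metrics <- function(C, N, p_draws) {
  stopifnot(length(C) == length(N), nrow(p_draws) == length(C))
  obs <- C / N
  pred <- rowMeans(p_draws)
  err <- pred - obs
  n_draws <- ncol(p_draws)
  covered <- vapply(seq_along(C), function(i) {
    counts <- stats::rbinom(n_draws, N[i], p_draws[i, ])
    lo <- stats::quantile(counts, 0.025, type = 1)
    hi <- stats::quantile(counts, 0.975, type = 1)
    C[i] >= lo && C[i] <= hi
  }, logical(1))
  correlation <- if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    NA_real_
  } else {
    stats::cor(pred, obs)
  }
  data.frame(n = length(C), bias = mean(err), rmse = sqrt(mean(err^2)),
             coverage = mean(covered), correlation = correlation)
}

#' Spatially stratified fivefold cross-validation of the wasting stage
#'
#' Full out-of-sample validation loop: for each spatial fold, the stacking
#' submodels and the geostatistical stage are refitted on the training folds
#' only, and predictive draws (including hyper-mode GP kriging, country
#' effects, nugget noise and the binomial layer) are evaluated at the
#' held-out clusters. Metrics are reported per fold and pooled.
#'
#' @param obs a `cluster_obs` data frame (point-located; expand polygons
#'   first).
#' @param world a `toy_world` supplying covariate values at cells.
#' @param k number of folds.
#' @param n_draws predictive draws per held-out observation.
#' @param seed integer seed.
#' @param priors a [prior_config()].
#' @param control a [fit_control()].
#' @param stack_config submodel hyperparameters for [stack_submodels()].
#' @return object of class `validation_report`: `per_fold` data frame,
#'   `pooled` one-row data frame, `folds`, `seed`.
#' @export
cross_validate <- function(obs, world, k = 5, n_draws = 300, seed = 1L,
                           priors = prior_config(),
                           control = fit_control(),
                           stack_config = list()) {
  covs <- colnames(world$covariates)
  obs <- cbind(obs, world$covariates[obs$cell, , drop = FALSE])
  obs$C <- obs$C_w
  folds <- spatial_folds(obs$admin1, k = k, seed = seed)
  per_fold <- list()
  all_pred <- vector("list", k)
  all_idx <- vector("list", k)
  for (f in seq_len(k)) {
    train <- obs[folds != f, , drop = FALSE]
    test <- obs[folds == f, , drop = FALSE]
    stacked <- stack_submodels(train, covs, newdata = test, k = 5,
                               seed = as.integer(seed) + 7L * f,
                               config = stack_config)
    train_sc <- cbind(train, stacked_covariates(stacked$oos))
    test_sc <- cbind(test, stacked_covariates(stacked$insample))
    f_stage <- stats::as.formula(paste("cbind(C_w, N - C_w) ~",
                                       paste(stacked$kinds,
                                             collapse = " + ")))
    fit <- fit_stage(f_stage, train_sc, priors = priors, control = control,
                     seed = as.integer(seed) + f, stage = "wasting")
    eta <- sample_stage(fit, test_sc, n_draws = n_draws,
                        seed = as.integer(seed) + 100L + f,
                        include_nugget = TRUE)
    t_idx <- match(test_sc$year, fit$years)
    p_draws <- t(vapply(seq_len(nrow(test_sc)), function(i) {
      stats::plogis(eta[i, t_idx[i], ])
    }, numeric(n_draws)))
    set.seed(as.integer(seed) + 200L + f)
    m <- holdout_metrics(test$C_w, test$N, p_draws)
    m$fold <- f
    per_fold[[f]] <- m
    all_pred[[f]] <- p_draws
    all_idx[[f]] <- which(folds == f)
  }
  per_fold <- do.call(rbind, per_fold)
  pooled_p <- do.call(rbind, all_pred)
  pooled_idx <- unlist(all_idx)
  set.seed(as.integer(seed) + 999L)
  pooled <- holdout_metrics(obs$C_w[pooled_idx], obs$N[pooled_idx], pooled_p)
  structure(list(per_fold = per_fold, pooled = pooled, folds = folds,
                 seed = as.integer(seed)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Spatially stratified", nrow(x$per_fold),
      "fold out-of-sample validation\n")
  cat(sprintf("  pooled (n = %d): bias %.4f | RMSE %.4f | 95%% coverage %.3f",
              x$pooled$n, x$pooled$bias, x$pooled$rmse, x$pooled$coverage))
  cat(sprintf(" | correlation %.3f\n", x$pooled$correlation))
  invisible(x)
}

#' Write a validation report to CSV and JSON
#' @param report a `validation_report`.
#' @param csv_path,json_path output files (either may be `NULL`).
#' @export
write_validation_report <- function(report, csv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(csv_path)) {
    pf <- cbind(scope = "fold", report$per_fold)
    pl <- cbind(scope = "pooled", report$pooled, fold = NA)
    utils::write.csv(rbind(pf, pl[names(pf)]), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_fold = report$per_fold,
                              pooled = report$pooled, seed = report$seed),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
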