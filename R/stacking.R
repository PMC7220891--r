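#' Assign observations to cross-validation folds
#'
#' Near-equal random folds (sizes differ by at most one), deterministic for a
#' given seed.
#'
#' @param n number of observations (>= k).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..k`.
#' @export
assign_folds <- function(n, k = 5, seed = 1L) {
  if (n < k) stop("need at least as many observations as folds",
                  call. = FALSE)
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(k), n))
}

# Clamp probabilities away from 0/1 before taking logits.
clamp_prob <- function(p, eps = 1e-6) pmin(1 - eps, pmax(eps, p))

#' Fit one ensemble submodel
#'
#' Fits one of the three submodel families to cluster-level binomial counts
#' on gridded covariates, honouring observation weights:
#' \describe{
#'   \item{gam}{binomial additive model with penalized thin-plate smooths per
#'     covariate (\pkg{mgcv}).}
#'   \item{brt}{gradient-boosted regression trees on binomial deviance
#'     (\pkg{xgboost}; labels are empirical proportions, instance weights are
#'     trial counts times observation weights).}
#'   \item{lasso}{L1-penalized logistic regression with the penalty chosen by
#'     internal cross-validation (\pkg{glmnet}).}
#' }
#' Constant covariates are dropped with a message before fitting.
#'
#' @param kind `"gam"`, `"brt"` or `"lasso"`.
#' @param data data frame with `C` (successes), `N` (trials), `weight_obs`
#'   and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param config list of hyperparameters: `gam_k` (basis size per smooth,
#'   default 5), `brt_rounds`/`brt_depth`/`brt_eta` (100, 3, 0.1),
#'   `lasso_nfolds` (5).
#' @param seed integer seed.
#' @return object of class `submodel` with a `$predict(newdata)` closure
#'   returning probabilities strictly inside (0, 1).
#' @export
fit_submodel <- function(kind = c("gam", "brt", "lasso"), data, covariates,
                         config = list(), seed = 1L) {
  kind <- match.arg(kind)
  cfg <- utils::modifyList(list(gam_k = 5, brt_rounds = 100, brt_depth = 3,
                                brt_eta = 0.1, lasso_nfolds = 5), config)
  keep <- vapply(covariates, function(v) stats::sd(data[[v]]) > 0,
                 logical(1))
  if (any(!keep)) {
    message("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "))
  }
  covariates <- covariates[keep]
  if (!length(covariates)) stop("no non-degenerate covariates", call. = FALSE)
  if (length(unique(data$C / data$N)) < 2) {
    stop("training data have a single outcome value", call. = FALSE)
  }
  set.seed(as.integer(seed))
  w <- data$weight_obs
  predictor <- switch(
    kind,
    gam = {
      smooths <- paste0("s(", covariates, ", k = ", cfg$gam_k, ")")
      f <- stats::as.formula(paste("cbind(C, N - C) ~",
                                   paste(smooths, collapse = " + ")))
      fit <- mgcv::gam(f, family = stats::binomial(), data = data,
                       weights = w)
      function(newdata) {
        as.numeric(stats::predict(fit, newdata, type = "response"))
      }
    },
    brt = {
      X <- as.matrix(data[covariates])
      d <- xgboost::xgb.DMatrix(X, label = data$C / data$N,
                                weight = data$N * w)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = cfg$brt_depth,
                      eta = cfg$brt_eta, nthread = 1,
                      seed = as.integer(seed)),
        data = d, nrounds = cfg$brt_rounds, verbose = 0)
      function(newdata) {
        stats::predict(fit, xgboost::xgb.DMatrix(
          as.matrix(newdata[covariates])))
      }
    },
    lasso = {
      X <- as.matrix(data[covariates])
      if (ncol(X) == 1) X <- cbind(X, 0)  # glmnet needs >= 2 columns
      foldid <- assign_folds(nrow(X), min(cfg$lasso_nfolds, nrow(X)),
                             seed = seed)
      fit <- glmnet::cv.glmnet(X, cbind(data$N - data$C, data$C),
                               family = "binomial", weights = w,
                               foldid = foldid)
      function(newdata) {
        Xn <- as.matrix(newdata[covariates])
        if (ncol(Xn) == 1) Xn <- cbind(Xn, 0)
        as.numeric(stats::predict(fit, Xn, s = "lambda.min",
                                  type = "response"))
      }
    })
  structure(list(kind = kind, covariates = covariates,
                 predict = function(newdata) {
                   clamp_prob(predictor(newdata))
                 }),
            class = "submodel")
}

#' Stacked-ensemble predictions for one model stage
#'
#' Fits the three submodels (`gam`, `brt`, `lasso`) with fivefold
#' cross-validation: per submodel, the five fold-fits give each observation an
#' out-of-sample predicted probability (from the fold-fit not trained on it),
#' and one full-data fit gives in-sample predictions at every prediction
#' location. The out-of-sample set is intended as the covariates of the
#' geostatistical fitting stage; the in-sample set as the covariates of its
#' prediction stage.
#'
#' @param data observation data frame (`C`, `N`, `weight_obs`, covariates).
#' @param covariates covariate column names.
#' @param newdata data frame of prediction locations carrying the covariate
#'   columns (e.g. one row per cell).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param config submodel hyperparameters, see [fit_submodel()].
#' @param kinds submodel families to include.
#' @return object of class `stacked_predictions`: `oos` (n x H matrix of
#'   out-of-sample probabilities), `insample` (rows of `newdata` x H),
#'   `folds`, `kinds`, `seed`, plus the full-data `fits`.
#' @export
stack_submodels <- function(data, covariates, newdata, k = 5, seed = 1L,
                            config = list(),
                            kinds = c("gam", "brt", "lasso")) {
  folds <- assign_folds(nrow(data), k, seed = seed)
  oos <- matrix(NA_real_, nrow(data), length(kinds),
                dimnames = list(NULL, kinds))
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    for (m in kinds) {
      fit <- fit_submodel(m, train, covariates, config,
                          seed = as.integer(seed) + f)
      oos[folds == f, m] <- fit$predict(test)
    }
  }
  fits <- lapply(stats::setNames(kinds, kinds), function(m) {
    fit_submodel(m, data, covariates, config, seed = as.integer(seed))
  })
  insample <- vapply(kinds, function(m) fits[[m]]$predict(newdata),
                     numeric(nrow(newdata)))
  structure(list(oos = oos, insample = insample, folds = folds,
                 kinds = kinds, seed = as.integer(seed), fits = fits),
            class = "stacked_predictions")
}

#' @export
print.stacked_predictions <- function(x, ...) {
  cat("Stacked predictions:", paste(x$kinds, collapse = ", "), "|",
      nrow(x$oos), "out-of-sample rows,", nrow(x$insample),
      "prediction rows,", max(x$folds), "folds\n")
  invisible(x)
}

#' Write stacked out-of-sample predictions to CSV
#' @param stacked a `stacked_predictions`.
#' @param path output file.
#' @export
write_stacked_oos <- function(stacked, path) {
  utils::write.csv(data.frame(obs = seq_len(nrow(stacked$oos)),
                              fold = stacked$folds, stacked$oos),
                   path, row.names = FALSE)
}
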