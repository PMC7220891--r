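#' Fit the seasonal adjustment model for WHZ
#'
#' Penalized additive model
#' `WHZ ~ s_cc(month) + s_tp(t) + factor(country)` fitted with \pkg{mgcv}:
#' a cyclic cubic regression spline over interview month (12 basis functions,
#' period 12), a low-rank thin-plate spline over interview time in months
#' since study start (4 basis functions) and country fixed effects. Smoothing
#' parameters are selected by generalized cross-validation. The country
#' effects and long-term trend are included only to avoid confounding while
#' the seasonal curve is fitted; only the periodic component is used in the
#' adjustment.
#'
#' @param records data frame with columns `whz` (or `z_col`), `month`, `t`,
#'   `country`.
#' @param k_month cyclic-cubic basis dimension (default 12).
#' @param k_trend thin-plate trend basis dimension (default 4).
#' @param z_col z-score column name.
#' @return object of class `seasonal_fit`: the \pkg{mgcv} fit, a seasonal
#'   evaluation function, the periodic mean of the fitted seasonal curve over
#'   one cycle and the basis configuration.
#' @export
fit_seasonal_model <- function(records, k_month = 12, k_trend = 4,
                               z_col = "whz") {
  d <- data.frame(whz = records[[z_col]], month = records$month,
                  t = records$t, country = factor(records$country))
  if (length(unique(d$month)) < 2) {
    stop("need at least two distinct interview months", call. = FALSE)
  }
  formula <- if (nlevels(d$country) > 1) {
    whz ~ s(month, bs = "cc", k = k_month) + s(t, bs = "tp", k = k_trend) +
      country
  } else {
    whz ~ s(month, bs = "cc", k = k_month) + s(t, bs = "tp", k = k_trend)
  }
  fit <- mgcv::gam(formula, data = d, method = "GCV.Cp",
                   knots = list(month = c(0.5, 12.5)))
  seasonal <- function(month) {
    nd <- data.frame(month = month, t = stats::median(d$t),
                     country = factor(levels(d$country)[1],
                                      levels = levels(d$country)))
    as.numeric(stats::predict(fit, nd, type = "terms",
                              terms = "s(month)"))
  }
  grid <- seq(0.5, 12.5, length.out = 481)[-481]
  periodic_mean <- mean(seasonal(grid))
  structure(list(gam = fit, seasonal = seasonal,
                 periodic_mean = periodic_mean,
                 k_month = k_month, k_trend = k_trend,
                 countries = levels(d$country)),
            class = "seasonal_fit")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  amp <- seasonal_amplitude(x)
  cat("Seasonal WHZ model: cyclic-cubic month spline (k =", x$k_month,
      "), thin-plate trend (k =", x$k_trend, "),",
      length(x$countries), "countries\n")
  cat("  fitted seasonal amplitude:", format(amp, digits = 4),
      "z-score units; periodic mean:", format(x$periodic_mean, digits = 4),
      "\n")
  invisible(x)
}

#' Amplitude of a fitted seasonal curve
#'
#' Half the peak-to-trough range of the fitted periodic component over one
#' cycle.
#' @param fit a `seasonal_fit`.
#' @return nonnegative scalar.
#' @export
seasonal_amplitude <- function(fit) {
  grid <- seq(0.5, 12.5, length.out = 481)[-481]
  s <- fit$seasonal(grid)
  (max(s) - min(s)) / 2
}

#' Seasonality-adjust WHZ records
#'
#' Subtracts the deviation of the fitted seasonal curve at the interview month
#' from its periodic mean:
#' `WHZ_adj = WHZ - (s_cc(month) - mean(s_cc))`. Neither country effects nor
#' the long-term trend enter the adjustment.
#'
#' @param records data frame with `month` and the z-score column.
#' @param fit a `seasonal_fit`.
#' @param z_col z-score column to adjust.
#' @return the records with an added `whz_adj` column.
#' @export
adjust_whz <- function(records, fit, z_col = "whz") {
  stopifnot(inherits(fit, "seasonal_fit"))
  s <- fit$seasonal(records$month)
  records$whz_adj <- records[[z_col]] - (s - fit$periodic_mean)
  records
}

#' Serialize a seasonal fit to JSON
#'
#' Stores coefficients, smoothing parameters and the evaluated seasonal curve
#' so the adjustment is reproducible without refitting.
#' @param fit a `seasonal_fit`.
#' @param path output file.
#' @export
write_seasonal_fit <- function(fit, path) {
  months <- seq(0.5, 12.45, by = 0.05)
  jsonlite::write_json(
    list(coefficients = as.list(stats::coef(fit$gam)),
         smoothing_parameters = as.numeric(fit$gam$sp),
         periodic_mean = fit$periodic_mean,
         k_month = fit$k_month, k_trend = fit$k_trend,
         seasonal_curve = list(month = months, value = fit$seasonal(months))),
    path, auto_unbox = TRUE, digits = NA)
}

#' Resample a polygon observation to population-weighted pseudo-points
#'
#' Polygon-referenced observations are stood in for by
#' `k = min(cap, max(1, round(ratio * n_cells)))` point locations sampled with
#' replacement from the polygon's cells with probability proportional to cell
#' population. Point weights are proportional to the population of the
#' sampled cells and normalized to sum to one, so each polygon contributes a
#' single observation's worth of information to a weighted pseudo-likelihood.
#'
#' @param polygon_cells data frame of the polygon's cells with columns
#'   `cell`, `x`, `y`, `pop`.
#' @param ratio pseudo-points per polygon cell (default 1/50, i.e. one point
#'   per 50 cells).
#' @param cap maximum number of pseudo-points per polygon.
#' @param seed integer seed (recorded in the output).
#' @return data frame of class `pseudo_points`: `cell`, `x`, `y`, `weight`
#'   (summing to 1), with attributes `seed`.
#' @export
resample_polygon <- function(polygon_cells, ratio = 1 / 50, cap = 100,
                             seed = 1L) {
  pos <- polygon_cells$pop > 0
  if (!any(pos)) {
    stop("polygon has no cell with positive population", call. = FALSE)
  }
  set.seed(as.integer(seed))
  k <- min(cap, max(1L, round(ratio * nrow(polygon_cells))))
  idx <- sample(which(pos), k, replace = TRUE,
                prob = polygon_cells$pop[pos])
  w <- polygon_cells$pop[idx]
  out <- data.frame(cell = polygon_cells$cell[idx],
                    x = polygon_cells$x[idx], y = polygon_cells$y[idx],
                    weight = w / sum(w))
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("pseudo_points", "data.frame")
  out
}

#' Expand polygon-referenced cluster observations into pseudo-points
#'
#' Applies [resample_polygon()] to every polygon-located row of a cluster
#' observation set: each pseudo-point inherits the polygon's counts and
#' carries `weight_obs` equal to its resampling weight (the binomial
#' log-likelihood term is multiplied by this weight during fitting). Point
#' observations pass through unchanged with `weight_obs = 1`.
#'
#' @param obs a `cluster_obs` data frame (may mix point and polygon rows).
#' @param world a `toy_world` supplying cell membership and population.
#' @param ratio,cap see [resample_polygon()].
#' @param seed integer seed.
#' @return a `cluster_obs` data frame with every row point-located.
#' @export
expand_polygon_obs <- function(obs, world, ratio = 1 / 50, cap = 100,
                               seed = 1L) {
  poly <- !is.na(obs$polygon_id) & obs$loc_type == "polygon"
  if (!any(poly)) return(obs)
  out <- list(obs[!poly, , drop = FALSE])
  prows <- which(poly)
  for (j in seq_along(prows)) {
    row <- obs[prows[j], , drop = FALSE]
    cells <- world$cells[world$cells$admin2 == row$polygon_id, ]
    pts <- resample_polygon(cells[, c("cell", "x", "y", "pop")],
                            ratio = ratio, cap = cap,
                            seed = as.integer(seed) + j)
    rep_row <- row[rep(1, nrow(pts)), , drop = FALSE]
    rep_row$cell <- pts$cell
    rep_row$x <- pts$x
    rep_row$y <- pts$y
    rep_row$loc_type <- "pseudo"
    rep_row$weight_obs <- row$weight_obs * pts$weight
    out[[j + 1]] <- rep_row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cluster_obs", "data.frame")
  res
}
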