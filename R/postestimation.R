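#' Mask barren and sparsely populated cells
#'
#' Cells whose land cover is "barren" or whose total population falls below
#' the threshold are set to `NA` in every year and draw; all other values are
#' untouched.
#'
#' @param surface numeric array with cells in the first dimension (vector,
#'   cells x years matrix, or cells x years x draws array).
#' @param landcover character vector per cell.
#' @param population total population per cell.
#' @param pop_threshold mask cells with population strictly below this
#'   (default 10 individuals per cell).
#' @return the surface with masked cells set to `NA`.
#' @export
apply_mask <- function(surface, landcover, population, pop_threshold = 10) {
  n_cells <- if (is.null(dim(surface))) length(surface) else dim(surface)[1]
  if (length(landcover) != n_cells || length(population) != n_cells) {
    stop("landcover/population layers do not match the surface's cell ",
         "dimension", call. = FALSE)
  }
  mask <- landcover == "barren" | population < pop_threshold
  if (is.null(dim(surface))) {
    surface[mask] <- NA_real_
  } else {
    idx <- slice.index(surface, 1) %in% which(mask)
    surface[idx] <- NA_real_
  }
  surface
}

#' Aggregate draw-level prevalence to administrative units
#'
#' Per draw and year, unit prevalence is the under-5 population-weighted mean
#' over the unit's unmasked member cells; affected-children counts are
#' prevalence times the unit's under-5 population, computed at draw level.
#' Summaries are the draw mean and the 2.5th/97.5th draw percentiles.
#'
#' @param draws a `posterior_draws` (cells x years x draws per category).
#' @param pop_u5 under-5 population per cell.
#' @param membership unit id per cell (e.g. admin2, admin1, country, or a
#'   constant for national); cells with `NA` membership are ignored.
#' @param categories which categories to aggregate.
#' @return data frame of class `admin_estimates`: `unit`, `year`, `category`,
#'   `mean`, `lower`, `upper`, `count`, `count_lower`, `count_upper`,
#'   `pop_u5`. Units with zero unmasked population are flagged with `NA`
#'   estimates.
#' @export
aggregate_draws <- function(draws, pop_u5, membership,
                            categories = c("p_wasting", "p_over",
                                           "p_normal")) {
  stopifnot(inherits(draws, "posterior_draws"))
  units <- sort(unique(membership[!is.na(membership)]))
  out <- list()
  for (cat_nm in categories) {
    a <- draws[[cat_nm]]
    for (u in units) {
      cells <- which(membership == u)
      for (ti in seq_along(draws$years)) {
        slab <- a[cells, ti, , drop = FALSE]   # cells x 1 x draws
        ok <- !is.na(slab[, 1, 1])
        wpop <- pop_u5[cells]
        if (!any(ok) || sum(wpop[ok]) <= 0) {
          est <- c(NA_real_, NA_real_, NA_real_)
          cnt <- c(NA_real_, NA_real_, NA_real_)
          totpop <- sum(wpop[ok])
        } else {
          w <- wpop[ok] / sum(wpop[ok])
          mat <- matrix(slab[ok, 1, ], nrow = sum(ok))
          prev <- colSums(mat * w)
          totpop <- sum(wpop[ok])
          est <- c(mean(prev), stats::quantile(prev, c(0.025, 0.975)))
          counts <- prev * totpop
          cnt <- c(mean(counts), stats::quantile(counts, c(0.025, 0.975)))
        }
        out[[length(out) + 1L]] <- data.frame(
          unit = u, year = draws$years[ti], category = sub("^p_", "", cat_nm),
          mean = est[1], lower = est[2], upper = est[3],
          count = cnt[1], count_lower = cnt[2], count_upper = cnt[3],
          pop_u5 = totpop)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("admin_estimates", "data.frame")
  res
}

#' Recency-weighted annualized rate of change (AROC)
#'
#' Per draw and cell, the AROC between adjacent years is the logit difference
#' `logit(p_t) - logit(p_{t-1})`; the weighted AROC averages these with
#' normalized recency weights `W_t = (t - t0 + 1)^gamma_w`, so larger
#' `gamma_w` concentrates weight on the most recent changes. Probabilities
#' exactly at 0 or 1 are clamped to `[1e-6, 1 - 1e-6]` with a warning. With
#' `aroc_type = "ratio"` the literal ratio reading
#' `logit(p_t / p_{t-1})` is used instead (for auditability only; the
#' projection formula assumes logit differences).
#'
#' @param p cells x years x draws array of prevalence draws.
#' @param years the years of the second dimension.
#' @param gamma_w recency-weight exponent, >= 0.
#' @param aroc_type `"logit_diff"` (default) or `"ratio"`.
#' @return cells x draws matrix of weighted AROC values (logit units per
#'   year).
#' @export
compute_aroc <- function(p, years, gamma_w = 1,
                         aroc_type = c("logit_diff", "ratio")) {
  aroc_type <- match.arg(aroc_type)
  if (gamma_w < 0) stop("`gamma_w` must be nonnegative", call. = FALSE)
  if (length(years) < 2) stop("need at least two years", call. = FALSE)
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    warning("prevalence values at 0 or 1 clamped to [1e-6, 1 - 1e-6]")
    dm <- dim(p)
    p <- pmin(1 - 1e-6, pmax(1e-6, p))
    dim(p) <- dm
  }
  T <- length(years)
  W <- (years[-1] - years[1] + 1)^gamma_w
  W <- W / sum(W)
  q <- if (aroc_type == "logit_diff") stats::qlogis(p) else p
  out <- 0
  for (ti in 2:T) {
    step <- if (aroc_type == "logit_diff") {
      q[, ti, , drop = FALSE] - q[, ti - 1, , drop = FALSE]
    } else {
      stats::qlogis(pmin(1 - 1e-6,
                         pmax(1e-6, p[, ti, , drop = FALSE] /
                                p[, ti - 1, , drop = FALSE])))
    }
    out <- out + W[ti - 1] * step
  }
  matrix(out, dim(p)[1], dim(p)[3])
}

#' Project prevalence forward at draw level
#'
#' `Proj = logit^-1(logit(p_base) + AROC * horizon)`, applied per draw and
#' cell, mirroring an 8-year projection from the final estimation year.
#'
#' @param p_base cells x draws matrix of base-year prevalence draws.
#' @param aroc cells x draws matrix from [compute_aroc()].
#' @param horizon projection horizon in years, >= 0 (default 8).
#' @return cells x draws matrix of projected prevalence.
#' @export
project_prevalence <- function(p_base, aroc, horizon = 8) {
  if (horizon < 0) stop("`horizon` must be nonnegative", call. = FALSE)
  if (!all(dim(p_base) == dim(aroc))) {
    stop("`p_base` and `aroc` draws are not aligned", call. = FALSE)
  }
  stats::plogis(stats::qlogis(pmin(1 - 1e-6, pmax(1e-6, p_base))) +
                  aroc * horizon)
}

#' Double-burden (DBM) classification of wasting and overweight prevalence
#'
#' Bands each prevalence into `[0,5)`, `[5,10)`, `[10,15)`, `[15,Inf)` percent
#' (lower edge inclusive) and assigns the double-burden level: `moderate` if
#' both conditions are at or above 5%, `high` if both at or above 10%,
#' `very_high` if both at or above 15%, otherwise `none`. Levels are nested:
#' the DBM level is set by the lower of the two bands.
#'
#' @param p_wasting,p_over prevalence values in `[0, 1]` (vectors of equal
#'   length).
#' @return data frame with `wasting_band`, `over_band` (factors) and `dbm`
#'   (factor `none < moderate < high < very_high`).
#' @export
classify_bands <- function(p_wasting, p_over) {
  if (any(p_wasting < 0 | p_wasting > 1 | p_over < 0 | p_over > 1,
          na.rm = TRUE)) {
    stop("prevalence values must lie in [0, 1]", call. = FALSE)
  }
  band_levels <- c("[0,5)", "[5,10)", "[10,15)", "[15,Inf)")
  band <- function(p) {
    cut(100 * p, c(0, 5, 10, 15, Inf), right = FALSE, labels = band_levels,
        include.lowest = TRUE)
  }
  bw <- band(p_wasting)
  bo <- band(p_over)
  lev <- pmin(as.integer(bw), as.integer(bo)) - 1L
  dbm <- factor(c("none", "moderate", "high", "very_high")[lev + 1L],
                levels = c("none", "moderate", "high", "very_high"),
                ordered = TRUE)
  data.frame(wasting_band = bw, over_band = bo, dbm = dbm)
}

#' WHO Global Nutrition Target check for wasting
#'
#' `TRUE` where wasting prevalence is strictly below 5% (the 2025 target).
#' @param p_wasting prevalence in `[0, 1]`.
#' @return logical vector.
#' @export
gnt_check <- function(p_wasting) {
  if (any(p_wasting < 0 | p_wasting > 1, na.rm = TRUE)) {
    stop("prevalence values must lie in [0, 1]", call. = FALSE)
  }
  p_wasting < 0.05
}
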