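# Truncated-normal sampler via inverse-CDF; vectorized over n.
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Draw a child WHZ given its planted category: a three-component mixture of
# truncated normals whose components live strictly inside the category bands
# (kept within +/- 4.5 so the default implausibility filter never bites).
draw_whz_given_category <- function(category) {
  n <- length(category)
  z <- numeric(n)
  w <- category == "wasted"; o <- category == "overweight"
  nm <- !(w | o)
  z[w] <- rtnorm(sum(w), -2.6, 0.5, -4.5, -2)
  z[o] <- rtnorm(sum(o), 2.6, 0.5, 2, 4.5)
  z[nm] <- rtnorm(sum(nm), 0, 1, -2, 2)
  z
}

# Invert the LMS transform: the weight whose z-score is `z` under (L, M, S).
lms_weight_for_z <- function(z, L, M, S) {
  ifelse(L != 0, M * (1 + L * S * z)^(1 / L), M * exp(S * z))
}

#' Simulate individual child survey records
#'
#' Places survey clusters at population-weighted random cells with random
#' interview month and year, then draws each child's weight-for-height z-score
#' (WHZ) from a continuous three-component mixture whose category masses at
#' the cluster's cell-year equal the latent truth's `(p_wasting, p_normal,
#' p_over)`, plus an additive seasonal term
#' `amplitude * sin(2 pi month / 12)`. Height, weight, age and sex are
#' back-computed through the toy LMS reference so that [compute_whz()]
#' recovers the planted WHZ to numerical precision.
#'
#' @param world a `toy_world`.
#' @param truth a `latent_truth` for the same world.
#' @param n_clusters number of survey clusters (>= 1).
#' @param children_per_cluster mean children sampled per cluster (Poisson
#'   around this mean, minimum 5); defaults to the world config's
#'   `cluster_size`.
#' @param seasonal_amplitude amplitude (z-score units) of the planted
#'   sinusoidal seasonal signal; >= 0.
#' @param seed integer seed.
#' @param years years in which clusters may be interviewed (default: all
#'   world years).
#'
#' @return a data frame of class `child_records` with one row per child:
#'   identifiers, location (`cell`, `x`, `y`, `loc_type`, `polygon_id`),
#'   `country`, `admin1`, `admin2`, `year`, `month`, `t` (months since study
#'   start), `sex`, `age`, `height`, `weight`, and generator ground truth
#'   `whz_planted` (the value `compute_whz` recovers) and `whz_base` (before
#'   the seasonal term).
#' @export
simulate_child_records <- function(world, truth, n_clusters = 200,
                                   children_per_cluster = NULL,
                                   seasonal_amplitude = 0.5, seed = 1L,
                                   years = world$years) {
  stopifnot(inherits(world, "toy_world"), inherits(truth, "latent_truth"))
  if (n_clusters < 1) stop("need at least one cluster", call. = FALSE)
  if (seasonal_amplitude < 0) {
    stop("`seasonal_amplitude` must be nonnegative", call. = FALSE)
  }
  if (is.null(children_per_cluster)) {
    children_per_cluster <- world$config$cluster_size
  }
  if (sum(world$cells$pop) <= 0) {
    stop("world has zero total population; cannot place clusters",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  cell_idx <- sample.int(nrow(world$cells), n_clusters, replace = TRUE,
                         prob = world$cells$pop)
  year <- sample(years, n_clusters, replace = TRUE)
  month <- sample.int(12L, n_clusters, replace = TRUE)
  n_child <- pmax(5L, stats::rpois(n_clusters, children_per_cluster))

  rows <- vector("list", n_clusters)
  for (cl in seq_len(n_clusters)) {
    i <- cell_idx[cl]
    ti <- match(year[cl], world$years)
    probs <- c(truth$p_wasting[i, ti], truth$p_normal[i, ti],
               truth$p_over[i, ti])
    nc <- n_child[cl]
    category <- sample(c("wasted", "normal", "overweight"), nc,
                       replace = TRUE, prob = probs)
    whz_base <- draw_whz_given_category(category)
    whz <- whz_base + seasonal_amplitude * sin(2 * pi * month[cl] / 12)
    sex <- sample(c("female", "male"), nc, replace = TRUE)
    age <- sample(0:59, nc, replace = TRUE)
    ref <- world$lms[match(paste(sex, age), paste(world$lms$sex,
                                                  world$lms$age_months)), ]
    rows[[cl]] <- data.frame(
      cluster_id = cl, child_id = NA_integer_, cell = world$cells$cell[i],
      x = world$cells$x[i], y = world$cells$y[i], loc_type = "point",
      polygon_id = NA_integer_, country = world$cells$country[i],
      admin1 = world$cells$admin1[i], admin2 = world$cells$admin2[i],
      year = year[cl], month = month[cl],
      t = (year[cl] - min(world$years)) * 12L + month[cl] - 1L,
      sex = sex, age = age, height = 65 + 0.8 * age,
      weight = lms_weight_for_z(whz, ref$L, ref$M, ref$S),
      whz_planted = whz, whz_base = whz_base,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$child_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("child_records", "data.frame")
  out
}

#' Convert a fraction of clusters to polygon-referenced observations
#'
#' Emulates surveys that report only the administrative unit of each cluster:
#' selected clusters lose their coordinates and gain the identifier of their
#' containing admin2 polygon. Record counts are untouched.
#'
#' @param records a `child_records` data frame.
#' @param fraction_polygon fraction of clusters to convert, in `[0, 1]`.
#' @param seed integer seed.
#' @return the records with `loc_type`, `cell`, `x`, `y`, `polygon_id`
#'   updated for the selected clusters.
#' @export
make_polygon_observations <- function(records, fraction_polygon, seed = 1L) {
  if (fraction_polygon < 0 || fraction_polygon > 1) {
    stop("`fraction_polygon` must be in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  ids <- unique(records$cluster_id)
  n_poly <- round(fraction_polygon * length(ids))
  if (n_poly == 0) return(records)
  chosen <- sample(ids, n_poly)
  sel <- records$cluster_id %in% chosen
  records$polygon_id[sel] <- records$admin2[sel]
  records$loc_type[sel] <- "polygon"
  records$cell[sel] <- NA_integer_
  records$x[sel] <- NA_real_
  records$y[sel] <- NA_real_
  records
}

#' Write child records to CSV
#' @param records a `child_records` data frame.
#' @param path output file.
#' @export
write_child_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
}

#' Read child records from CSV
#'
#' @param path CSV file with the column schema written by
#'   [write_child_records()]; a named `column_map` can translate external
#'   column names onto it.
#' @param column_map optional named character vector `c(internal = external)`.
#' @return a `child_records` data frame.
#' @export
read_child_records <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      names(df)[names(df) == column_map[[nm]]] <- nm
    }
  }
  needed <- c("cluster_id", "weight", "height", "age", "sex", "month", "year")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("child record file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("child_records", "data.frame")
  df
}
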