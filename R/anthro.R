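#' Compute weight-for-height z-scores via the LMS transform
#'
#' Applies the Box-Cox power (LMS) transform with the sex- and age-specific
#' reference rows: `z = ((x/M)^L - 1) / (L S)` when `L != 0` and
#' `z = log(x/M) / S` when `L = 0`, where `x` is the child's weight.
#'
#' @param records data frame with `weight`, `sex`, `age` columns (one row per
#'   child).
#' @param ref LMS reference data frame with columns `sex`, `age_months`, `L`,
#'   `M`, `S`; lookup keys must be unique.
#' @return numeric vector of z-scores.
#' @export
compute_whz <- function(records, ref) {
  key <- paste(ref$sex, ref$age_months)
  if (anyDuplicated(key)) {
    stop("LMS reference has duplicate (sex, age) rows", call. = FALSE)
  }
  idx <- match(paste(records$sex, floor(records$age)), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("no LMS reference row for sex=", records$sex[bad], ", age=",
         floor(records$age[bad]), " months", call. = FALSE)
  }
  L <- ref$L[idx]; M <- ref$M[idx]; S <- ref$S[idx]
  x <- records$weight
  ifelse(L != 0, ((x / M)^L - 1) / (L * S), log(x / M) / S)
}

#' Classify a weight-for-height z-score into ordinal categories
#'
#' A child is wasted if more than two standard deviations below the reference
#' median (`z < -2`) and overweight if more than two above (`z > 2`); values
#' exactly at a cutoff are classified normal (strict inequalities).
#'
#' @param z finite numeric vector of z-scores.
#' @return character vector in `{"wasted", "normal", "overweight"}`.
#' @export
classify_whz <- function(z) {
  if (any(!is.finite(z))) stop("z-scores must be finite", call. = FALSE)
  ifelse(z < -2, "wasted", ifelse(z > 2, "overweight", "normal"))
}

#' Remove implausible or incomplete child records
#'
#' Drops records with missing required fields (sex, age, weight, height) or
#' with WHZ outside plausibility bounds, and returns an exclusion log giving
#' the reason per dropped record. The default bounds of (-5, 5) follow the
#' common anthropometric flagging convention for weight-for-height.
#'
#' @param records child-record data frame with a `whz` column (or supply
#'   `whz`).
#' @param bounds length-2 numeric `(lo, hi)`, `lo < hi`.
#' @param whz optional z-score vector; defaults to `records$whz`.
#' @return list with `records` (kept rows) and `exclusions` (data frame:
#'   `child_id`, `reason`).
#' @export
filter_implausible <- function(records, bounds = c(-5, 5), whz = records$whz) {
  if (bounds[1] >= bounds[2]) stop("bounds must satisfy lo < hi",
                                   call. = FALSE)
  id <- if ("child_id" %in% names(records)) records$child_id
        else seq_len(nrow(records))
  required <- intersect(c("sex", "age", "weight", "height"), names(records))
  missing_field <- if (length(required)) {
    Reduce(`|`, lapply(records[required], is.na))
  } else {
    rep(FALSE, nrow(records))
  }
  implausible <- !missing_field &
    (is.na(whz) | whz < bounds[1] | whz > bounds[2])
  reason <- rep(NA_character_, nrow(records))
  reason[implausible] <- "implausible_z"
  reason[missing_field] <- "missing_field"
  drop <- !is.na(reason)
  list(records = records[!drop, , drop = FALSE],
       exclusions = data.frame(child_id = id[drop], reason = reason[drop],
                               stringsAsFactors = FALSE))
}

#' Collapse child records to cluster-level binomial counts
#'
#' Produces, per cluster-year, the two-stage continuation-ratio counts:
#' `N` children sampled, `C_w` wasted, `N_cond = N - C_w` non-wasted, and
#' `C_o` overweight among the non-wasted. With
#' `conditioning = "overweight_first"` the roles are reversed (wasting
#' conditioned on not being overweight), provided for sensitivity checks.
#'
#' @param records child-record data frame with `cluster_id`, `year`, location
#'   columns and a z-score column.
#' @param z_col name of the z-score column to classify (default `"whz"`).
#' @param conditioning `"wasting_first"` (default) or `"overweight_first"`.
#' @return data frame of class `cluster_obs` with one row per cluster-year
#'   and columns `cluster_id`, `cell`, `x`, `y`, `loc_type`, `polygon_id`,
#'   `country`, `admin1`, `admin2`, `year`, `N`, `C_w`, `N_cond`, `C_o`,
#'   `weight_obs` (1 for point observations). Empty clusters are dropped with
#'   a message.
#' @export
collapse_clusters <- function(records, z_col = "whz",
                              conditioning = c("wasting_first",
                                               "overweight_first")) {
  conditioning <- match.arg(conditioning)
  if (!z_col %in% names(records)) {
    stop("records have no column `", z_col, "`", call. = FALSE)
  }
  keep <- !is.na(records[[z_col]])
  if (any(!keep)) {
    message("dropping ", sum(!keep), " records with missing z-scores")
    records <- records[keep, , drop = FALSE]
  }
  category <- classify_whz(records[[z_col]])
  key <- interaction(records$cluster_id, records$year, drop = TRUE)
  first <- !duplicated(key)
  meta_cols <- intersect(c("cluster_id", "cell", "x", "y", "loc_type",
                           "polygon_id", "country", "admin1", "admin2",
                           "year"), names(records))
  out <- records[first, meta_cols, drop = FALSE]
  out$N <- as.integer(tapply(rep(1L, length(key)), key, sum)[as.character(
    key[first])])
  n_w <- tapply(category == "wasted", key, sum)
  n_o <- tapply(category == "overweight", key, sum)
  w <- as.integer(n_w[as.character(key[first])])
  o <- as.integer(n_o[as.character(key[first])])
  if (conditioning == "wasting_first") {
    out$C_w <- w
    out$N_cond <- out$N - w
    out$C_o <- o
  } else {
    out$C_w <- o              # stage 1 models overweight
    out$N_cond <- out$N - o
    out$C_o <- w              # stage 2: wasting among non-overweight
  }
  out$weight_obs <- 1
  rownames(out) <- NULL
  class(out) <- c("cluster_obs", "data.frame")
  out
}

#' Write cluster observations to CSV
#' @param obs a `cluster_obs` data frame.
#' @param path output file.
#' @export
write_cluster_obs <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
}

#' Read cluster observations from CSV
#' @param path CSV written by [write_cluster_obs()].
#' @return a `cluster_obs` data frame.
#' @export
read_cluster_obs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("cluster_obs", "data.frame")
  df
}
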