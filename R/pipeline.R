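#' Pipeline configuration
#'
#' Bundles the stage configurations and per-stage seeds of the end-to-end
#' analysis (simulate world and records, seasonality-adjust, stack, fit both
#' stages, predict, aggregate, project, validate). The configuration
#' round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]) and is stamped into every artifact via its hash.
#'
#' @param world a [world_config()].
#' @param truth latent-truth parameters (see [default_truth_params()]).
#' @param records list: `n_clusters`, `seasonal_amplitude`,
#'   `fraction_polygon`.
#' @param seasonal list: `k_month`, `k_trend`.
#' @param stacking list: `k` folds and submodel `config`.
#' @param priors a [prior_config()] or preset name for [prior_preset()].
#' @param fit list of [fit_control()] arguments.
#' @param projection list: `gamma_w`, `horizon`.
#' @param mask list: `pop_threshold`.
#' @param n_draws posterior draws for prediction.
#' @param validation list: `k` folds and `n_draws`.
#' @param seeds named list of per-stage integer seeds.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(world = world_config(), truth = NULL,
                            records = list(n_clusters = 150,
                                           seasonal_amplitude = 0.5,
                                           fraction_polygon = 0.1),
                            seasonal = list(k_month = 12, k_trend = 4),
                            stacking = list(k = 5, config = list()),
                            priors = "main",
                            fit = list(support_spacing = 3),
                            projection = list(gamma_w = 1, horizon = 8),
                            mask = list(pop_threshold = 10),
                            n_draws = 200,
                            validation = list(k = 5, n_draws = 200),
                            seeds = list(world = 11, truth = 12, records = 13,
                                         stack = 14, fit = 15, predict = 16,
                                         validate = 17)) {
  if (is.character(priors)) priors <- prior_preset(priors)
  structure(list(world = world, truth = truth, records = records,
                 seasonal = seasonal, stacking = stacking, priors = priors,
                 fit = fit, projection = projection, mask = mask,
                 n_draws = n_draws, validation = validation, seeds = seeds),
            class = "pipeline_config")
}

#' Hash of a configuration (or any serializable object)
#'
#' MD5 of the canonical JSON serialization; used to stamp artifacts so stale
#' or tampered upstream files are detected.
#' @param x object to hash.
#' @return hex string.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Write / read a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    world = do.call(world_config, raw$world),
    records = raw$records, seasonal = raw$seasonal,
    stacking = raw$stacking,
    priors = do.call(prior_config, raw$priors),
    fit = raw$fit, projection = raw$projection, mask = raw$mask,
    n_draws = raw$n_draws, validation = raw$validation, seeds = raw$seeds)
  cfg
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

pipeline_stages <- c("simulate", "prepare", "stack", "fit", "predict",
                     "aggregate", "project", "validate", "report")

#' Run the end-to-end pipeline
#'
#' Executes the analysis stages in order up to `stage` (or all of them),
#' writing each stage's artifacts under `outdir` together with a manifest
#' recording the configuration hash, per-stage seeds and per-file MD5 hashes.
#' Stages are deterministic given the configuration, so a rerun with an
#' unchanged configuration reproduces every artifact; if a previously written
#' artifact no longer matches its manifest hash the run refuses and names the
#' file.
#'
#' @param config a `pipeline_config` or path to a YAML file.
#' @param stage last stage to execute: one of `"simulate"`, `"prepare"`,
#'   `"stack"`, `"fit"`, `"predict"`, `"aggregate"`, `"project"`,
#'   `"validate"`, `"report"`, or `"all"`.
#' @param outdir output directory.
#' @param verify_manifest check existing artifacts against the manifest
#'   before overwriting.
#' @return invisibly, a list with the in-memory artifacts of the executed
#'   stages.
#' @export
run_pipeline <- function(config = pipeline_config(), stage = "all",
                         outdir = file.path(tempdir(), "dbmgeo-run"),
                         verify_manifest = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, c(pipeline_stages, "all"))
  last <- if (stage == "all") length(pipeline_stages)
          else match(stage, pipeline_stages)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass_deep(config))
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list(config_hash = hash, files = list())
  }
  if (verify_manifest && length(manifest$files)) {
    for (f in names(manifest$files)) {
      p <- file.path(outdir, f)
      if (file.exists(p) &&
          !identical(unname(tools::md5sum(p)), manifest$files[[f]])) {
        stop("artifact `", f, "` does not match the manifest hash; ",
             "remove it or rerun from scratch", call. = FALSE)
      }
    }
  }
  record_file <- function(path) {
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
  }
  art <- list(config = config, config_hash = hash)

  # simulate -----------------------------------------------------------------
  art$world <- make_toy_world(config$world, seed = config$seeds$world)
  truth_params <- if (is.null(config$truth)) default_truth_params()
                  else config$truth
  art$truth <- simulate_latent_truth(art$world, truth_params,
                                     seed = config$seeds$truth)
  art$records <- simulate_child_records(
    art$world, art$truth, n_clusters = config$records$n_clusters,
    seasonal_amplitude = config$records$seasonal_amplitude,
    seed = config$seeds$records)
  if (config$records$fraction_polygon > 0) {
    art$records <- make_polygon_observations(
      art$records, config$records$fraction_polygon,
      seed = config$seeds$records + 1L)
  }
  if (last >= 1) {
    write_child_records(art$records, file.path(outdir, "child_records.csv"))
    record_file(file.path(outdir, "child_records.csv"))
    write_world(art$world, file.path(outdir, "world"))
  }
  if (last >= 2) {
    # prepare: z-scores, implausibility filter, seasonal adjustment,
    # collapse, polygon expansion
    art$records$whz <- compute_whz(art$records, art$world$lms)
    flt <- filter_implausible(art$records)
    art$records <- flt$records
    art$exclusions <- flt$exclusions
    art$seasonal_fit <- fit_seasonal_model(
      art$records, k_month = config$seasonal$k_month,
      k_trend = config$seasonal$k_trend)
    art$records <- adjust_whz(art$records, art$seasonal_fit)
    obs <- collapse_clusters(art$records, z_col = "whz_adj")
    art$cluster_obs <- expand_polygon_obs(obs, art$world,
                                          seed = config$seeds$records + 2L)
    write_cluster_obs(art$cluster_obs, file.path(outdir, "cluster_obs.csv"))
    record_file(file.path(outdir, "cluster_obs.csv"))
    write_seasonal_fit(art$seasonal_fit, file.path(outdir,
                                                   "seasonal_fit.json"))
    record_file(file.path(outdir, "seasonal_fit.json"))
  }
  if (last >= 3) {
    covs <- colnames(art$world$covariates)
    obs <- cbind(art$cluster_obs,
                 art$world$covariates[art$cluster_obs$cell, , drop = FALSE])
    cells_df <- as.data.frame(art$world$covariates)
    obs_w <- obs; obs_w$C <- obs_w$C_w
    art$stack_wasting <- stack_submodels(obs_w, covs, newdata = cells_df,
                                         k = config$stacking$k,
                                         seed = config$seeds$stack,
                                         config = config$stacking$config)
    obs_o <- obs[obs$N_cond > 0, , drop = FALSE]
    obs_o$C <- obs_o$C_o; obs_o$N <- obs_o$N_cond
    art$stack_cond <- stack_submodels(obs_o, covs, newdata = cells_df,
                                      k = config$stacking$k,
                                      seed = config$seeds$stack + 1L,
                                      config = config$stacking$config)
    art$.obs <- obs; art$.obs_o <- obs_o
    write_stacked_oos(art$stack_wasting,
                      file.path(outdir, "stacked_oos_wasting.csv"))
    record_file(file.path(outdir, "stacked_oos_wasting.csv"))
  }
  if (last >= 4) {
    ctl <- do.call(fit_control, config$fit)
    kinds <- art$stack_wasting$kinds
    dat_w <- cbind(art$.obs, stacked_covariates(art$stack_wasting$oos))
    art$fit_wasting <- fit_stage(
      stats::as.formula(paste("cbind(C_w, N - C_w) ~",
                              paste(kinds, collapse = " + "))),
      dat_w, priors = config$priors, control = ctl,
      seed = config$seeds$fit, stage = "wasting")
    dat_o <- cbind(art$.obs_o, stacked_covariates(art$stack_cond$oos))
    art$fit_cond <- fit_stage(
      stats::as.formula(paste("cbind(C_o, N_cond - C_o) ~",
                              paste(kinds, collapse = " + "))),
      dat_o, priors = config$priors, control = ctl,
      seed = config$seeds$fit + 1L, stage = "overweight_cond")
    fit_json <- file.path(outdir, "stage_fits.json")
    jsonlite::write_json(
      list(config_hash = hash,
           wasting = as.list(coef(art$fit_wasting)),
           overweight_cond = as.list(coef(art$fit_cond)),
           log_marginal = c(wasting = art$fit_wasting$log_marginal,
                            cond = art$fit_cond$log_marginal)),
      fit_json, auto_unbox = TRUE, digits = NA)
    record_file(fit_json)
  }
  if (last >= 5) {
    cells <- art$world$cells
    nd_w <- cbind(cells, stacked_covariates(art$stack_wasting$insample))
    nd_o <- cbind(cells, stacked_covariates(art$stack_cond$insample))
    art$draws <- sample_posterior(art$fit_wasting, art$fit_cond, nd_w, nd_o,
                                  n_draws = config$n_draws,
                                  seed = config$seeds$predict)
    for (nm in c("p_wasting", "p_over", "p_normal")) {
      art$draws[[nm]] <- apply_mask(art$draws[[nm]], cells$landcover,
                                    cells$pop,
                                    config$mask$pop_threshold)
    }
    smry <- summary(art$draws)
    utils::write.csv(smry, file.path(outdir, "prevalence_summary.csv"),
                     row.names = FALSE)
    record_file(file.path(outdir, "prevalence_summary.csv"))
  }
  if (last >= 6) {
    cells <- art$world$cells
    art$admin2_estimates <- aggregate_draws(art$draws, cells$pop_u5,
                                            cells$admin2)
    art$national_estimates <- aggregate_draws(art$draws, cells$pop_u5,
                                              cells$country)
    utils::write.csv(art$admin2_estimates,
                     file.path(outdir, "admin2_estimates.csv"),
                     row.names = FALSE)
    record_file(file.path(outdir, "admin2_estimates.csv"))
  }
  if (last >= 7) {
    T <- length(art$draws$years)
    base <- art$draws$p_wasting[, T, ]
    aroc_w <- compute_aroc(art$draws$p_wasting, art$draws$years,
                           gamma_w = config$projection$gamma_w)
    art$projection_wasting <- project_prevalence(
      base, aroc_w, horizon = config$projection$horizon)
    base_o <- art$draws$p_over[, T, ]
    aroc_o <- compute_aroc(art$draws$p_over, art$draws$years,
                           gamma_w = config$projection$gamma_w)
    art$projection_over <- project_prevalence(
      base_o, aroc_o, horizon = config$projection$horizon)
    art$dbm <- classify_bands(rowMeans(base), rowMeans(base_o))
    art$gnt_projected <- gnt_check(rowMeans(art$projection_wasting))
    dbm_df <- cbind(cell = art$world$cells$cell, art$dbm,
                    gnt_projected = art$gnt_projected)
    utils::write.csv(dbm_df, file.path(outdir, "dbm_classes.csv"),
                     row.names = FALSE)
    record_file(file.path(outdir, "dbm_classes.csv"))
  }
  if (last >= 8) {
    art$validation <- cross_validate(
      art$cluster_obs, art$world, k = config$validation$k,
      n_draws = config$validation$n_draws, seed = config$seeds$validate,
      priors = config$priors, control = do.call(fit_control, config$fit),
      stack_config = config$stacking$config)
    write_validation_report(art$validation,
                            csv_path = file.path(outdir, "validation.csv"),
                            json_path = file.path(outdir, "validation.json"))
    record_file(file.path(outdir, "validation.csv"))
    record_file(file.path(outdir, "validation.json"))
  }
  if (last >= 9) {
    report <- list(
      config_hash = hash,
      national = art$national_estimates,
      dbm_counts = as.list(table(art$dbm$dbm)),
      gnt_projected_fraction = mean(art$gnt_projected, na.rm = TRUE),
      validation = art$validation$pooled)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    record_file(file.path(outdir, "report.json"))
  }
  manifest$config_hash <- hash
  manifest$seeds <- config$seeds
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(art)
}
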