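# End-to-end pipeline: simulate (or load) -> engineer covariates -> fit ->
# predict -> change map -> evaluate, with a checksum manifest of every
# artifact written.

#' Default run configuration
#'
#' @param seed Root seed; all stage seeds derive from it deterministically.
#' @param output_dir Output directory.
#' @param model Model id (see \code{make_configs}).
#' @param extent_m,cell_size_m,n_years Domain of the simulated study.
#' @param covariate_names Fixed-effect covariates (post-selection).
#' @param presence_mode Presence-likelihood support (see
#'   \code{build_model_data}).
#' @param n_prediction_samples Posterior samples for surfaces.
#' @param evaluate Run WAIC + coverage report.
#' @param mesh_edge Inner maximum mesh edge in meters (default extent/10).
#' @param outer_maxit Outer-optimizer evaluation budget for the fit.
#' @return RunConfig list (serializable with yaml).
#' @export
run_config <- function(seed = 1L, output_dir = tempfile("fernfusion_run_"),
                       model = "M21", extent_m = 2000, cell_size_m = 100,
                       n_years = 10L,
                       covariate_names = c("bio01", "tpi", "rao_vertical",
                                           "dist_river"),
                       presence_mode = "all_cells",
                       n_prediction_samples = 100L, evaluate = TRUE,
                       mesh_edge = NULL, outer_maxit = 200L) {
  list(seed = seed, output_dir = output_dir, model = model,
       extent_m = extent_m, cell_size_m = cell_size_m, n_years = n_years,
       covariate_names = covariate_names, presence_mode = presence_mode,
       n_prediction_samples = n_prediction_samples, evaluate = evaluate,
       mesh_edge = mesh_edge, outer_maxit = outer_maxit)
}

#' Run the full analysis pipeline
#'
#' @param cfg RunConfig list (see \code{run_config}) or path to a YAML file
#'   holding one.
#' @return Invisibly, a list with the artifacts directory, the fit, the
#'   prediction surface, the change map and (optionally) the evaluation
#'   report; a \code{manifest.csv} with md5 checksums covers every file
#'   written.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(stage)
    message(sprintf("[%s] %s", format(Sys.time() - t0, digits = 3), stage))

  log_stage("simulate")
  sim <- fern_simulate(seed = cfg$seed, extent_m = cfg$extent_m,
                       cell_size_m = cfg$cell_size_m, n_years = cfg$n_years,
                       mesh_edge = cfg$mesh_edge %||% NULL)
  write_simulation(sim, file.path(cfg$output_dir, "data"))

  log_stage("engineer covariates")
  wide <- stats::reshape(
    sim$covariates$table[sim$covariates$table$name %in% cfg$covariate_names, ],
    idvar = c("cell_id", "year"), timevar = "name", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  std <- standardize_covariates(wide[cfg$covariate_names])
  long_std <- do.call(rbind, lapply(cfg$covariate_names, function(nm)
    data.frame(cell_id = wide$cell_id, year = wide$year, name = nm,
               value = std$table[[nm]])))
  extra <- sim$covariates$table[!(sim$covariates$table$name %in% cfg$covariate_names), ]
  covs <- rbind(long_std, extra)

  log_stage(sprintf("fit %s", cfg$model))
  config <- make_configs()[[cfg$model]]
  data <- list(domain = sim$domain, mesh = sim$mesh, covariates = covs,
               counts = sim$obs$counts,
               covariate_names = cfg$covariate_names,
               presence_mode = cfg$presence_mode)
  if (config$data_fusion) data$presences <- sim$obs$presences
  fit <- fit_isdm(config, data,
                  options = fit_options(tie_species_hypers = TRUE,
                                        outer_maxit = cfg$outer_maxit %||% 200L),
                  seed = cfg$seed)

  log_stage("predict")
  surf <- predict_intensity(fit, n_samples = cfg$n_prediction_samples,
                            seed = cfg$seed + 10L, return_samples = TRUE)
  utils::write.csv(as.data.frame(surf), file.path(cfg$output_dir, "surface.csv"),
                   row.names = FALSE)

  log_stage("change map")
  cm <- change_map(surf, min(sim$domain$years), max(sim$domain$years))
  utils::write.csv(cm, file.path(cfg$output_dir, "change_map.csv"),
                   row.names = FALSE)

  report <- NULL
  if (isTRUE(cfg$evaluate)) {
    log_stage("evaluate")
    w <- waic(fit, n_samples = 100L, seed = cfg$seed + 20L)
    cov_rep <- coverage_report(fit, n_samples = 100L, seed = cfg$seed + 21L)
    report <- list(waic = w, coverage = cov_rep)
    utils::write.csv(cov_rep$per_species,
                     file.path(cfg$output_dir, "coverage_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(waic = w$waic, p_waic = w$p_waic,
                              lppd = w$lppd, loglik = fit$loglik),
                         file.path(cfg$output_dir, "fit_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  yaml::write_yaml(cfg, file.path(cfg$output_dir, "run_config.yaml"))
  hi <- hyper_intervals(fit)
  if (nrow(hi)) utils::write.csv(hi, file.path(cfg$output_dir, "hyperparameters.csv"),
                                 row.names = FALSE)
  files <- setdiff(list.files(cfg$output_dir, recursive = TRUE), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = as.vector(tools::md5sum(file.path(cfg$output_dir, files))))
  utils::write.csv(manifest, file.path(cfg$output_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(dir = cfg$output_dir, fit = fit, surface = surf,
                 change_map = cm, report = report, manifest = manifest))
}
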