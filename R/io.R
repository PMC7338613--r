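# Configuration files, run drivers and reproducibility plumbing.
#
# One YAML config drives each run type. Configs are validated against a
# fixed schema of known keys before any computation; every run writes a
# manifest (config hash, seed, package version) next to its outputs,
# and outputs are written atomically (tempfile + rename).

CONFIG_SCHEMA <- list(
  simulate = list(
    required = c("regimen", "T0", "t_end"),
    optional = c("params", "dt", "rtol", "atol", "cap", "ref_amount")),
  generate = list(
    required = c("arms"),
    optional = c("initial_volume_range", "measurement_days",
                 "noise_sd_log", "seed", "truth")),
  fit = list(
    required = c("data"),
    optional = c("n_starts", "refine_top", "seed", "loss", "maxiter",
                 "bounds_log10", "near_opt_frac", "outlier_policy")),
  predict = list(
    required = c("regimens"),
    optional = c("params", "T0_grid", "t_end", "dt", "rebound_factor",
                 "suppression_factor"))
)

#' Read and validate a run configuration
#'
#' @param path YAML file with exactly one top-level block named
#'   `simulate`, `generate`, `fit` or `predict`. Unknown keys are
#'   rejected.
#' @return The validated config list, with attribute `kind` and
#'   `config_hash` (md5 of the file).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  kinds <- intersect(names(cfg), names(CONFIG_SCHEMA))
  if (length(kinds) != 1 || length(cfg) != 1) {
    stop("config must contain exactly one of: ",
         paste(names(CONFIG_SCHEMA), collapse = ", "))
  }
  kind <- kinds[1]
  block <- cfg[[kind]]
  schema <- CONFIG_SCHEMA[[kind]]
  unknown <- setdiff(names(block), c(schema$required, schema$optional))
  if (length(unknown)) {
    stop("unknown config key(s) in '", kind, "': ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(schema$required, names(block))
  if (length(missing)) {
    stop("missing required config key(s) in '", kind, "': ",
         paste(missing, collapse = ", "))
  }
  structure(block, kind = kind,
            config_hash = unname(tools::md5sum(path)))
}

write_manifest <- function(out_dir, config, seed = NULL) {
  manifest <- list(
    kind = attr(config, "kind"),
    config_hash = attr(config, "config_hash"),
    seed = seed,
    package = "metroimmune",
    version = as.character(utils::packageVersion("metroimmune")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
}

config_params <- function(block) {
  if (is.null(block$params)) default_truth_params()
  else as_parameter_set(block$params)
}

#' Run a simulation from a config
#'
#' @param config A config from [read_run_config()] with a `simulate`
#'   block, or a path to one.
#' @param out_dir Output directory (created if needed); writes
#'   `trajectory.csv` (+ JSON sidecar) and `manifest.json`.
#' @return The `mi_trajectory`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(attr(config, "kind") == "simulate")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sched <- build_schedule(config$regimen, config$t_end,
                          ref_amount = config$ref_amount %||% 1)
  traj <- simulate_tumor(config_params(config), sched,
                         T0 = config$T0, t_end = config$t_end,
                         dt = config$dt %||% 0.1,
                         rtol = config$rtol %||% 1e-8,
                         atol = config$atol %||% 1e-10,
                         cap = config$cap %||% 1e8)
  write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
  write_manifest(out_dir, config)
  invisible(traj)
}

#' Generate a synthetic cohort from a config
#'
#' @param config A `generate` config (or path): `arms` is a named map
#'   regimen -> n subjects.
#' @param out_dir Output directory; writes `cohort.csv` (+ truth
#'   sidecar) and `manifest.json`.
#' @param seed Optional seed overriding the config's.
#' @return The `mi_cohort`, invisibly.
#' @export
run_generate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(attr(config, "kind") == "generate")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec(
    arms = unlist(config$arms),
    initial_volume_range = config$initial_volume_range %||% c(300, 1000),
    measurement_days = config$measurement_days %||% seq(0, 45, 3),
    noise_sd_log = config$noise_sd_log %||% 0.15,
    seed = seed %||% config$seed %||% 1,
    truth = if (is.null(config$truth)) default_truth_params()
            else as_parameter_set(config$truth))
  cohort <- generate_cohort(spec)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  write_manifest(out_dir, config, seed = spec$seed)
  invisible(cohort)
}

#' Fit the model to a cohort from a config
#'
#' @param config A `fit` config (or path): `data` is the cohort CSV
#'   path (relative paths resolve against the config's directory if
#'   read from file, else the working directory).
#' @param out_dir Output directory; writes `fits.csv`,
#'   `best_fit.json`, `residual_report.csv` and `manifest.json`.
#' @param seed Optional seed overriding the config's.
#' @return The `mi_fit_list`, invisibly.
#' @export
run_fit <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(attr(config, "kind") == "fit")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- read_cohort(config$data)
  bounds <- if (is.null(config$bounds_log10)) default_fit_bounds()
            else matrix(unlist(config$bounds_log10), ncol = 2,
                        byrow = TRUE, dimnames = list(PAR_NAMES, NULL))
  cfg <- fit_config(bounds = bounds,
                    n_starts = config$n_starts %||% 200,
                    refine_top = config$refine_top,
                    seed = seed %||% config$seed %||% 1,
                    loss = config$loss %||% "log_volume_sse",
                    near_opt_frac = config$near_opt_frac %||% 0.01,
                    maxiter = config$maxiter %||% 50,
                    outlier_policy = config$outlier_policy %||% "none")
  fits <- multistart_fit(data, cfg)
  write_csv_atomic(fits_table(fits), file.path(out_dir, "fits.csv"))
  bf <- best_fit(fits)
  jsonlite::write_json(
    list(params = params_to_list(bf$params), objective = bf$objective,
         converged = bf$converged, near_optimal = bf$near_optimal,
         seed = cfg$seed),
    file.path(out_dir, "best_fit.json"), auto_unbox = TRUE, digits = NA)
  flagged <- flag_outliers(data, bf, policy = cfg$outlier_policy)
  report <- attr(flagged, "subject_residuals")
  if (is.null(report)) {
    report <- data.frame(subject_id = unique(data$subject_id),
                         outlier = FALSE)
  }
  write_csv_atomic(report, file.path(out_dir, "residual_report.csv"))
  write_manifest(out_dir, config, seed = cfg$seed)
  invisible(fits)
}

#' Predict regimen outcomes from a config
#'
#' @param config A `predict` config (or path).
#' @param out_dir Output directory; writes `escape_report.csv`,
#'   `kill_attribution.csv`, `arm_summaries.csv` and `manifest.json`.
#' @return The `mi_prediction`, invisibly.
#' @export
run_predict <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(attr(config, "kind") == "predict")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pred <- predict_regimens(
    config_params(config), unlist(config$regimens),
    T0_grid = unlist(config$T0_grid) %||% c(300, 650, 1000),
    t_end = config$t_end %||% 45, dt = config$dt %||% 0.05,
    rebound_factor = config$rebound_factor %||% 2,
    suppression_factor = config$suppression_factor %||% 0.5)
  df <- as.data.frame(pred)
  write_csv_atomic(df[, c("regimen", "T0", "status", "rebound_day",
                          "escaped", "final_volume", "min_volume")],
                   file.path(out_dir, "escape_report.csv"))
  write_csv_atomic(df[, c("regimen", "T0", "drug_kill", "immune_kill")],
                   file.path(out_dir, "kill_attribution.csv"))
  summaries <- attr(pred, "summaries")
  arm_df <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(regimen = nm, as.data.frame(s))
  }))
  write_csv_atomic(arm_df, file.path(out_dir, "arm_summaries.csv"))
  write_manifest(out_dir, config)
  invisible(pred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
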