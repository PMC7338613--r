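# Synthetic longitudinal tumor-volume cohorts.
#
# Emulates the design of the GL261 metronomic-dosing experiments: 4-12
# tumors per arm, initial volumes 300-1,000 mm^3 at first injection,
# doses of 140 or 210 mg/kg on the named schedules, and dynamics
# generated by the model itself with multiplicative lognormal
# measurement noise. Inter-subject heterogeneity is limited to the
# initial volume: one population parameter set drives every subject.

#' Describe a synthetic cohort
#'
#' @param arms Named integer vector: number of subjects per regimen,
#'   e.g. `c("untreated" = 8, "CPA/6-days" = 8)`; names must resolve in
#'   the regimen registry (or be supplied via `regimens`). Defaults to
#'   the full experimental panel at `n_per_arm` subjects.
#' @param n_per_arm Default arm size when `arms` is not given (4-12
#'   unless `relax_sizes`).
#' @param initial_volume_range Initial tumor volumes (mm^3) drawn
#'   uniformly from this range at first injection.
#' @param measurement_days Sampling grid in days (default every 3 days,
#'   day 0 to 45).
#' @param noise_sd_log SD of multiplicative lognormal measurement noise:
#'   observed = true * exp(eps), eps ~ N(0, noise_sd_log^2), i.i.d.
#' @param volume_floor_mm3 Detection floor (mm^3): observed volumes are
#'   censored from below at this value, emulating the caliper
#'   measurement limit (default 1). Set to 0 to disable.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @param truth Ground-truth `mi_params` (default
#'   [default_truth_params()]).
#' @param regimens Optional named list of `mi_regimen_spec` overriding
#'   the registry for the arm names.
#' @param relax_sizes Allow arm sizes outside 4-12.
#' @return A list of class `mi_cohort_spec`.
#' @export
cohort_spec <- function(arms = NULL, n_per_arm = 8,
                        initial_volume_range = c(300, 1000),
                        measurement_days = seq(0, 45, by = 3),
                        noise_sd_log = 0.15, volume_floor_mm3 = 1,
                        seed = 1, truth = default_truth_params(),
                        regimens = NULL, relax_sizes = FALSE) {
  if (is.null(arms)) {
    arms <- stats::setNames(rep(n_per_arm, length(experimental_arm_names())),
                            experimental_arm_names())
  }
  if (is.null(names(arms)) || any(names(arms) == "")) {
    stop("arms must be a named vector (regimen name -> n subjects)")
  }
  arms <- vapply(arms, as.integer, integer(1))
  if (!relax_sizes && (any(arms < 4) || any(arms > 12))) {
    stop("arm sizes must be within 4-12 (use relax_sizes = TRUE to override)")
  }
  if (length(initial_volume_range) != 2 ||
      initial_volume_range[1] <= 0 ||
      initial_volume_range[1] > initial_volume_range[2]) {
    stop("initial_volume_range must satisfy 0 < low <= high")
  }
  if (noise_sd_log < 0) stop("noise_sd_log must be >= 0")
  measurement_days <- sort(unique(as.numeric(measurement_days)))
  if (measurement_days[1] != 0) {
    stop("measurement_days must start at day 0 (the first injection)")
  }
  for (nm in names(arms)) {
    if (is.null(regimens[[nm]])) regimen(nm)  # errors if unknown
  }
  if (volume_floor_mm3 < 0) stop("volume_floor_mm3 must be >= 0")
  structure(list(arms = arms,
                 initial_volume_range = as.numeric(initial_volume_range),
                 measurement_days = measurement_days,
                 noise_sd_log = noise_sd_log,
                 volume_floor_mm3 = volume_floor_mm3,
                 seed = as.integer(seed),
                 truth = as_parameter_set(truth), regimens = regimens),
            class = "mi_cohort_spec")
}

cohort_schedule <- function(spec, arm_name) {
  t_end <- max(spec$measurement_days)
  rs <- if (!is.null(spec$regimens[[arm_name]])) spec$regimens[[arm_name]]
        else regimen(arm_name)
  build_schedule(rs, t_end)
}

#' Qualitative preflight check of a truth parameter set
#'
#' Checks that the intended ground truth reproduces the two anchor
#' behaviors of the experimental system: untreated tumors grow, and the
#' every-6-day reference regimen regresses (final volume below
#' baseline) from a mid-range initial volume.
#'
#' @param truth An `mi_params`.
#' @param T0 Initial volume used for the check (mm^3).
#' @param t_end Horizon (days).
#' @return Logical; `TRUE` when both behaviors hold. Attributes
#'   `untreated_grows` and `q6d_regresses` carry the individual checks.
#' @export
check_truth_behavior <- function(truth, T0 = 650, t_end = 45) {
  unt <- simulate_tumor(truth, dose_schedule(label = "untreated"),
                        T0 = T0, t_end = t_end, dt = 0.5)
  q6 <- simulate_tumor(truth, build_schedule("CPA/6-days", t_end),
                       T0 = T0, t_end = t_end, dt = 0.5)
  grows <- unt$states[nrow(unt$states), "T"] > T0
  regresses <- !q6$overflow && q6$states[nrow(q6$states), "T"] < T0
  structure(grows && regresses,
            untreated_grows = unname(grows),
            q6d_regresses = unname(regresses))
}

#' Generate a synthetic tumor-volume cohort
#'
#' For each subject the initial volume is drawn uniformly from
#' `initial_volume_range`, the truth trajectory is simulated under the
#' arm's schedule, and observed volumes are the true volumes perturbed
#' by i.i.d. multiplicative lognormal noise. Deterministic given
#' `spec$seed`.
#'
#' @param spec An `mi_cohort_spec`.
#' @return A data frame of class `mi_cohort` with columns `subject_id`,
#'   `arm`, `day`, `volume_mm3` and `volume_true`, plus attributes
#'   `truth` (the ground-truth parameter set) and `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "mi_cohort_spec")) stop("spec must be an mi_cohort_spec")
  pf <- check_truth_behavior(spec$truth,
                             T0 = mean(spec$initial_volume_range),
                             t_end = max(spec$measurement_days))
  if (!pf) {
    warning("truth parameters fail the qualitative preflight (",
            "untreated grows: ", attr(pf, "untreated_grows"),
            ", Q6D regresses: ", attr(pf, "q6d_regresses"), ")")
  }
  days <- spec$measurement_days
  t_end <- max(days)
  rng <- spec$initial_volume_range
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  out <- list()
  sid <- 0L
  for (arm_name in names(spec$arms)) {
    sched <- cohort_schedule(spec, arm_name)
    for (j in seq_len(spec$arms[[arm_name]])) {
      sid <- sid + 1L
      T0 <- stats::runif(1, rng[1], rng[2])
      traj <- simulate_tumor(spec$truth, sched, T0 = T0, t_end = t_end,
                             times = days)
      keep_days <- days[days <= max(traj$times) + 1e-9]  # overflow-truncated
      true_v <- trajectory_at(traj, keep_days, "T")
      eps <- stats::rnorm(length(keep_days), 0, spec$noise_sd_log)
      out[[sid]] <- data.frame(
        subject_id = sprintf("%s_%02d", gsub("[^0-9A-Za-z.-]+", "-",
                                             arm_name), j),
        arm = arm_name, day = keep_days,
        volume_mm3 = pmax(true_v * exp(eps), spec$volume_floor_mm3),
        volume_true = true_v,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  structure(tab, truth = spec$truth, spec = spec,
            class = c("mi_cohort", "data.frame"))
}

validate_measurement_table <- function(data) {
  need <- c("subject_id", "arm", "day", "volume_mm3")
  if (!all(need %in% names(data))) {
    stop("measurement table needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(data) == 0) stop("measurement table is empty")
  if (any(data$volume_mm3 <= 0)) stop("volumes must be > 0")
  key <- paste(data$subject_id, data$day)
  if (anyDuplicated(key)) stop("(subject_id, day) pairs must be unique")
  # rows may arrive in any order; consumers sort per subject
  invisible(data)
}

#' Write a cohort table to CSV (plus a truth sidecar when available)
#' @param data A measurement table (`mi_cohort` or plain data frame).
#' @param path CSV path; for synthetic cohorts the truth parameters are
#'   written to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  validate_measurement_table(data)
  write_csv_atomic(as.data.frame(data), path)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(list(truth = params_to_list(truth)),
                         paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#' @param path CSV path.
#' @return An `mi_cohort` data frame; the `truth` attribute is restored
#'   from the sidecar when present.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurement_table(tab)
  sidecar <- paste0(path, ".truth.json")
  truth <- NULL
  if (file.exists(sidecar)) {
    truth <- as_parameter_set(jsonlite::read_json(sidecar,
                                                  simplifyVector = TRUE)$truth)
  }
  structure(tab, truth = truth, class = c("mi_cohort", "data.frame"))
}
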