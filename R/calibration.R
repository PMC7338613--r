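# Population calibration: one parameter set fitted jointly to all arms.
#
# The default objective is the pooled sum of squared log-volume
# residuals over every subject and time point. Volumes span orders of
# magnitude between regressing and escaping arms, so the log loss
# weighs arms comparably; a single population parameter set (no
# per-subject or per-schedule adjustment) is fitted, with only each
# subject's measured baseline volume entering as its initial condition.
#
# Multistart: initial guesses are drawn log-uniformly within bounds (to
# sample several orders of magnitude), optionally screened by one
# objective evaluation, and refined with bounded Levenberg-Marquardt
# least squares on the log10-parameter scale.

#' Calibration configuration
#'
#' @param bounds 15 x 2 matrix of per-parameter (low, high) bounds on
#'   the log10 scale, rownames the parameter names. Default -4..4
#'   (1e-4 to 1e4) for every parameter.
#' @param n_starts Number of multistart initial guesses.
#' @param refine_top Refine only the `refine_top` best starts after a
#'   one-evaluation screening pass (`NULL` refines all). Screening keeps
#'   large multistarts affordable; every draw still gets one objective
#'   evaluation.
#' @param seed RNG seed for the start draws.
#' @param loss `"log_volume_sse"` (default) or `"relative_sse"`.
#' @param near_opt_frac Fits within this fraction of the best objective
#'   are flagged as the near-optimal family (default 0.01, i.e. 1%).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param rtol,atol Integrator tolerances used during fitting (looser
#'   than simulation defaults, for speed).
#' @param penalty Finite objective penalty added per subject whose
#'   simulation fails or overflows; keeps the objective defined
#'   everywhere.
#' @param outlier_policy `"none"` or `"robust_flag"` (see
#'   [flag_outliers()]).
#' @param volume_floor_mm3 Detection floor (mm^3) applied to both
#'   observed and simulated volumes before the log residual, matching
#'   the generator's measurement censoring (default 1).
#' @return A list of class `mi_fit_config`.
#' @export
fit_config <- function(bounds = default_fit_bounds(), n_starts = 200,
                       refine_top = NULL, seed = 1,
                       loss = c("log_volume_sse", "relative_sse"),
                       near_opt_frac = 0.01, maxiter = 50,
                       rtol = 1e-6, atol = 1e-8, penalty = 1e12,
                       outlier_policy = c("none", "robust_flag"),
                       volume_floor_mm3 = 1) {
  loss <- match.arg(loss)
  outlier_policy <- match.arg(outlier_policy)
  bounds <- as.matrix(bounds)
  if (!identical(dim(bounds), c(15L, 2L))) stop("bounds must be 15 x 2")
  if (is.null(rownames(bounds))) rownames(bounds) <- PAR_NAMES
  bounds <- bounds[PAR_NAMES, , drop = FALSE]
  if (any(!is.finite(bounds)) || any(bounds[, 1] >= bounds[, 2])) {
    stop("bounds must be finite with low < high")
  }
  n_starts <- as.integer(n_starts)
  if (n_starts < 1) stop("n_starts must be >= 1")
  structure(list(bounds = bounds, n_starts = n_starts,
                 refine_top = refine_top, seed = as.integer(seed),
                 loss = loss, near_opt_frac = near_opt_frac,
                 maxiter = maxiter, rtol = rtol, atol = atol,
                 penalty = penalty, outlier_policy = outlier_policy,
                 volume_floor_mm3 = volume_floor_mm3),
            class = "mi_fit_config")
}

#' Default fitting bounds: 1e-4 to 1e4 on every parameter
#' @return 15 x 2 matrix of log10 bounds.
#' @export
default_fit_bounds <- function() {
  matrix(c(rep(-4, 15), rep(4, 15)), ncol = 2,
         dimnames = list(PAR_NAMES, c("low", "high")))
}

# Precompute per-subject fitting inputs: schedule, days, log volumes,
# baseline. Subjects must be measured from day 0 (first injection), and
# the baseline volume is the simulation's initial tumor volume.
prepare_fit_data <- function(data, regimens = NULL,
                             volume_floor_mm3 = 1) {
  validate_measurement_table(data)
  subjects <- split(seq_len(nrow(data)), data$subject_id)
  sched_cache <- list()
  prep <- lapply(subjects, function(idx) {
    d <- data[idx, ]
    d <- d[order(d$day), ]
    if (d$day[1] != 0) {
      stop("subject ", d$subject_id[1],
           ": measurements must start at day 0 (treatment start)")
    }
    arm <- d$arm[1]
    t_end <- max(d$day)
    key <- paste(arm, t_end)
    if (is.null(sched_cache[[key]])) {
      rs <- if (!is.null(regimens[[arm]])) regimens[[arm]] else regimen(arm)
      sched_cache[[key]] <<- build_schedule(rs, t_end)
    }
    list(id = d$subject_id[1], arm = arm, days = d$day,
         volumes = d$volume_mm3,
         log_volumes = log(pmax(d$volume_mm3, volume_floor_mm3)),
         floor = volume_floor_mm3,
         T0 = d$volume_mm3[1], t_end = t_end,
         schedule = sched_cache[[key]])
  })
  unname(prep)
}

# Residual vector for one subject at one parameter set; NULL on
# simulation failure/overflow (the callers substitute a flat penalty —
# a graded, failure-time-dependent residual was tried and measurably
# degraded both Levenberg-Marquardt convergence and runtime).
subject_residuals <- function(params, sub, loss, rtol, atol) {
  # capture.output: the solver's Fortran core prints step-size
  # diagnostics for pathological parameter sets; those starts are
  # penalized, not reported line by line.
  traj <- NULL
  utils::capture.output(
    traj <- tryCatch(
      suppressWarnings(
        simulate_tumor(params, sub$schedule, T0 = sub$T0,
                       t_end = sub$t_end, times = sub$days,
                       rtol = rtol, atol = atol, neg_tol = 1e-6)),
      error = function(e) NULL),
    type = "output")
  if (is.null(traj) || traj$overflow) return(NULL)
  sim <- pmax(trajectory_at(traj, sub$days, "T"),
              max(sub$floor, 1e-9))
  if (loss == "log_volume_sse") sub$log_volumes - log(sim)
  else (pmax(sub$volumes, sub$floor) - sim) / pmax(sub$volumes, sub$floor)
}

#' Pooled fitting objective
#'
#' Sum over all subjects and time points of squared residuals between
#' observed and simulated tumor volume (log scale by default). Each
#' subject is simulated from its own measured baseline volume with all
#' other states zero; subjects whose simulation fails or overflows
#' contribute a large finite `penalty`.
#'
#' @param params An `mi_params` (or coercible).
#' @param data A measurement table (see [generate_cohort()]); arm labels
#'   must resolve in the regimen registry or `regimens`.
#' @param loss `"log_volume_sse"` or `"relative_sse"`.
#' @param regimens Optional named list of `mi_regimen_spec` for
#'   non-registry arm labels.
#' @param bounds Optional log10 bounds; parameters outside them are an
#'   error.
#' @param penalty Added per failing subject.
#' @param rtol,atol Integrator tolerances.
#' @param volume_floor_mm3 Detection floor applied to observed and
#'   simulated volumes (see [fit_config()]).
#' @return Nonnegative scalar; attribute `n_penalized` counts failing
#'   subjects.
#' @export
fit_objective <- function(params, data, loss = "log_volume_sse",
                          regimens = NULL, bounds = NULL,
                          penalty = 1e12, rtol = 1e-6, atol = 1e-8,
                          volume_floor_mm3 = 1) {
  params <- as_parameter_set(params)
  if (!is.null(bounds)) {
    lp <- log10(unclass(params))
    if (any(lp < bounds[, 1] - 1e-12) || any(lp > bounds[, 2] + 1e-12)) {
      stop("parameters outside bounds: ",
           paste(PAR_NAMES[lp < bounds[, 1] | lp > bounds[, 2]],
                 collapse = ", "))
    }
  }
  prep <- prepare_fit_data(data, regimens, volume_floor_mm3)
  objective_prepared(params, prep, loss, penalty, rtol, atol)
}

objective_prepared <- function(params, prep, loss, penalty, rtol, atol) {
  total <- 0
  n_pen <- 0L
  for (sub in prep) {
    r <- subject_residuals(params, sub, loss, rtol, atol)
    if (is.null(r)) {
      total <- total + penalty
      n_pen <- n_pen + 1L
    } else {
      total <- total + sum(r^2)
    }
  }
  structure(total, n_penalized = n_pen)
}

# Stacked residual vector across subjects for Levenberg-Marquardt; a
# failing subject contributes a constant large residual per point so
# the vector length never changes.
residuals_prepared <- function(params, prep, loss, rtol, atol,
                               fail_resid = 1e3) {
  unlist(lapply(prep, function(sub) {
    r <- subject_residuals(params, sub, loss, rtol, atol)
    if (is.null(r)) rep(fail_resid, length(sub$days)) else r
  }), use.names = FALSE)
}

#' Multistart population fit
#'
#' Draws `cfg$n_starts` log-uniform initial guesses within the bounds,
#' evaluates the objective at each (screening), refines the
#' `cfg$refine_top` best (default: all) with bounded
#' Levenberg-Marquardt on the log10-parameter scale, and returns the
#' refined fits sorted by objective. The near-optimal family — fits
#' within `cfg$near_opt_frac` (default 1%) of the best objective — is
#' flagged. Fully reproducible given `cfg$seed`.
#'
#' @param data A measurement table.
#' @param cfg An `mi_fit_config`.
#' @param starts Optional explicit start points (an `mi_params`, a list
#'   of them, or a matrix with 15 named columns, linear scale)
#'   overriding the random draws.
#' @param regimens Optional named list of `mi_regimen_spec` for
#'   non-registry arm labels.
#' @return An `mi_fit_list`: list with `results` (list of `mi_fit`,
#'   sorted ascending by objective, each with `params`, `objective`,
#'   `start`, `converged`, `near_optimal`, per-arm residual RMS),
#'   `screening` (data frame of all start objectives) and `cfg`.
#' @export
multistart_fit <- function(data, cfg = fit_config(), starts = NULL,
                           regimens = NULL) {
  prep <- prepare_fit_data(data, regimens, cfg$volume_floor_mm3)
  lb <- cfg$bounds[, 1]; ub <- cfg$bounds[, 2]

  if (is.null(starts)) {
    old_seed <- globalenv()$.Random.seed
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(cfg$seed)
    start_mat <- matrix(stats::runif(cfg$n_starts * 15, min = rep(lb, each = cfg$n_starts),
                                     max = rep(ub, each = cfg$n_starts)),
                        ncol = 15, dimnames = list(NULL, PAR_NAMES))
  } else {
    if (inherits(starts, "mi_params")) starts <- list(starts)
    if (is.list(starts)) {
      starts <- do.call(rbind, lapply(starts, function(p)
        unclass(as_parameter_set(p))))
    }
    start_mat <- log10(as.matrix(starts)[, PAR_NAMES, drop = FALSE])
    if (any(start_mat < rep(lb, each = nrow(start_mat))) ||
        any(start_mat > rep(ub, each = nrow(start_mat)))) {
      stop("supplied starts fall outside the bounds")
    }
  }

  obj_fun <- function(lp) {
    objective_prepared(validate_params(10^lp), prep, cfg$loss,
                       cfg$penalty, cfg$rtol, cfg$atol)
  }
  res_fun <- function(lp) {
    residuals_prepared(validate_params(10^lp), prep, cfg$loss,
                       cfg$rtol, cfg$atol)
  }

  screen_obj <- apply(start_mat, 1, obj_fun)
  ord <- order(screen_obj)
  k <- if (is.null(cfg$refine_top)) length(ord)
       else min(cfg$refine_top, length(ord))
  refine_idx <- ord[seq_len(k)]

  results <- lapply(refine_idx, function(i) {
    lp0 <- start_mat[i, ]
    lm <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = lp0, lower = lb, upper = ub,
                           fn = res_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = cfg$maxiter))),
      error = function(e) NULL)
    if (is.null(lm)) {
      return(structure(list(params = validate_params(10^lp0),
                            objective = unclass(screen_obj[i]),
                            start = validate_params(10^lp0),
                            converged = FALSE, info = NA_integer_,
                            message = "local refinement failed",
                            niter = 0L, start_index = i),
                       class = "mi_fit"))
    }
    pars <- validate_params(10^lm$par)
    obj <- objective_prepared(pars, prep, cfg$loss, cfg$penalty,
                              cfg$rtol, cfg$atol)
    structure(list(params = pars, objective = as.numeric(obj),
                   n_penalized = attr(obj, "n_penalized"),
                   start = validate_params(10^lp0),
                   converged = lm$info %in% 1:4, info = lm$info,
                   message = lm$message, niter = lm$niter,
                   start_index = i),
              class = "mi_fit")
  })

  if (all(vapply(results, function(r) !r$converged &&
                 r$message == "local refinement failed", logical(1)))) {
    stop("all multistart refinements failed")
  }

  results <- results[order(vapply(results, `[[`, numeric(1), "objective"))]
  best <- results[[1]]$objective
  results <- lapply(results, function(r) {
    r$near_optimal <- r$objective <= best * (1 + cfg$near_opt_frac)
    r$arm_rms <- arm_residual_rms(r$params, prep, cfg)
    r
  })
  structure(list(results = results,
                 screening = data.frame(start = seq_len(nrow(start_mat)),
                                        objective = as.numeric(screen_obj),
                                        refined = seq_len(nrow(start_mat))
                                                  %in% refine_idx),
                 cfg = cfg),
            class = "mi_fit_list")
}

arm_residual_rms <- function(params, prep, cfg) {
  arms <- vapply(prep, `[[`, character(1), "arm")
  res_by_arm <- lapply(split(prep, arms), function(subs) {
    unlist(lapply(subs, function(sub) {
      r <- subject_residuals(params, sub, cfg$loss, cfg$rtol, cfg$atol)
      if (is.null(r)) NA_real_ else r
    }))
  })
  vapply(res_by_arm, function(r) sqrt(mean(r^2)), numeric(1))
}

#' @export
print.mi_fit_list <- function(x, ...) {
  objs <- vapply(x$results, `[[`, numeric(1), "objective")
  n_no <- sum(vapply(x$results, `[[`, logical(1), "near_optimal"))
  cat(sprintf(
    "<mi_fit_list> %d start(s) screened, %d refined; best objective %.6g\n",
    nrow(x$screening), length(x$results), objs[1]))
  cat(sprintf("  near-optimal family (within %.0f%%): %d fit(s)\n",
              100 * x$cfg$near_opt_frac, n_no))
  invisible(x)
}

#' Best fit of a multistart run
#' @param fits An `mi_fit_list`.
#' @return The `mi_fit` with the smallest objective.
#' @export
best_fit <- function(fits) fits$results[[1]]

#' @export
print.mi_fit <- function(x, ...) {
  cat(sprintf("<mi_fit> objective %.6g (%s)\n", x$objective,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  print(x$params)
  invisible(x)
}

#' One-row-per-start summary of a multistart fit
#' @param fits An `mi_fit_list`.
#' @return Data frame: the 15 parameters, objective, converged and
#'   near-optimal flags, one row per refined start.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(fits$results, function(r) {
    data.frame(t(unclass(r$params)), objective = r$objective,
               converged = r$converged, near_optimal = r$near_optimal,
               start_index = r$start_index)
  }))
}

#' Flag outlier subjects against a fitted model
#'
#' Policy `"robust_flag"`: each subject is summarized by the median of
#' its absolute log-residuals against the fitted curves; a subject is
#' flagged when that summary lies more than `threshold` robust standard
#' deviations (MAD-based) above the cohort median AND exceeds
#' `min_abs` log units (so well-fit cohorts with negligible dispersion
#' are never flagged; a zero MAD flags nothing below `min_abs`). Flags
#' are annotations only — rows are never dropped automatically.
#'
#' @param data A measurement table.
#' @param fit An `mi_fit` (needed for `"robust_flag"`).
#' @param policy `"none"` or `"robust_flag"`.
#' @param threshold Robust z-score threshold (default 3).
#' @param min_abs Minimum median absolute log-residual for a flag
#'   (default 0.1, about a 10% volume deviation).
#' @param regimens Optional regimen overrides, as in [fit_objective()].
#' @return `data` with a logical `outlier` column; attribute
#'   `subject_residuals` holds the per-subject summaries.
#' @export
flag_outliers <- function(data, fit = NULL,
                          policy = c("none", "robust_flag"),
                          threshold = 3, min_abs = 0.1, regimens = NULL) {
  policy <- match.arg(policy)
  validate_measurement_table(data)
  data <- as.data.frame(data)
  if (policy == "none") {
    data$outlier <- FALSE
    return(data)
  }
  if (is.null(fit)) stop("policy 'robust_flag' needs a fit")
  prep <- prepare_fit_data(data, regimens)
  med_abs <- vapply(prep, function(sub) {
    r <- subject_residuals(fit$params, sub, "log_volume_sse", 1e-6, 1e-8)
    if (is.null(r)) Inf else stats::median(abs(r))
  }, numeric(1))
  names(med_abs) <- vapply(prep, `[[`, character(1), "id")
  center <- stats::median(med_abs[is.finite(med_abs)])
  scale <- stats::mad(med_abs[is.finite(med_abs)])
  flagged <- if (scale == 0) {
    med_abs > pmax(min_abs, center)
  } else {
    med_abs > center + threshold * scale & med_abs > min_abs
  }
  data$outlier <- unname(flagged[data$subject_id])
  attr(data, "subject_residuals") <-
    data.frame(subject_id = names(med_abs), median_abs_log_residual =
                 unname(med_abs), outlier = unname(flagged))
  data
}
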