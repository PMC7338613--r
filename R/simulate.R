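# Event-aware simulation of the five-state model.
#
# Doses are impulsive: integration proceeds segment by segment between
# dose times with u = 0, and at each event the drug state C is
# incremented by the bolus amount. The state stored AT an event time is
# the post-dose value (cadlag convention); the pre-dose limits are kept
# in a side table.

#' Simulate the tumor-immune-drug model under a dosing schedule
#'
#' Integrates the five ODE states from the initial condition
#' `(C, T, I, X, Y)(0) = (0, T0, 0, 0, 0)` — all states zero except the
#' tumor — applying each dose of `schedule` as an instantaneous
#' increment of C. Uses `deSolve`'s stiff-capable adaptive solver
#' (`lsodar`) with a compiled right-hand side and a terminal root at the
#' tumor overflow cap.
#'
#' @param params An `mi_params` parameter set.
#' @param schedule An `mi_schedule`; events after `t_end` are ignored.
#' @param T0 Initial tumor volume (mm^3), > 0.
#' @param t_end Simulation horizon in days.
#' @param dt Output grid resolution in days (default 0.1).
#' @param times Optional explicit output times (overrides `dt`); event
#'   times are always added internally.
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @param cap Tumor-volume overflow cap (mm^3). When T reaches the cap
#'   the simulation terminates early and the trajectory is flagged
#'   (`overflow = TRUE`), never silently truncated.
#' @param neg_tol States may undershoot 0 by at most this much
#'   (integrator noise, clipped to 0); a larger undershoot is an error.
#' @param maxsteps Maximum internal solver steps per output interval;
#'   lower it to fail fast on pathological parameter sets (as the
#'   calibration objective does).
#' @return An object of class `mi_trajectory`: list with `times`,
#'   `states` (matrix, columns C, T, I, X, Y; values at dose times are
#'   post-dose), `pre_dose` (pre-dose states at event times), `schedule`,
#'   `params`, `overflow`, `overflow_time`.
#' @export
simulate_tumor <- function(params, schedule = dose_schedule(), T0,
                           t_end, dt = 0.1, times = NULL,
                           rtol = 1e-8, atol = 1e-10,
                           cap = 1e8, neg_tol = 1e-9, maxsteps = 5000) {
  params <- as_parameter_set(params)
  if (!inherits(schedule, "mi_schedule")) stop("schedule must be an mi_schedule")
  if (!is.finite(T0) || T0 <= 0) stop("T0 must be > 0")
  if (T0 >= cap) stop("T0 must be below the overflow cap")
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0")

  ev <- schedule[schedule$time <= t_end, , drop = FALSE]
  if (is.null(times)) {
    grid <- seq(0, t_end, by = dt)
    if (t_end - grid[length(grid)] > 1e-9) grid <- c(grid, t_end)
  } else {
    grid <- sort(unique(as.numeric(times)))
    if (any(grid < 0) || any(grid > t_end + 1e-9)) {
      stop("output times must lie in [0, t_end]")
    }
    if (grid[1] > 0) grid <- c(0, grid)
    if (t_end - grid[length(grid)] > 1e-9) grid <- c(grid, t_end)
  }
  grid <- sort(unique(round(c(grid, ev$time), 9)))

  y <- c(C = 0, T = unname(T0), I = 0, X = 0, Y = 0)
  pre_dose <- NULL
  # day-0 dose applied directly to the initial condition
  if (nrow(ev) && ev$time[1] == 0) {
    pre_dose <- rbind(pre_dose, c(time = 0, y))
    y[["C"]] <- y[["C"]] + ev$amount[1]
  }

  bounds <- sort(unique(c(0, ev$time[ev$time > 0], t_end)))
  parms <- c(unclass(params), cap)
  rows <- NULL
  overflow <- FALSE
  overflow_time <- NA_real_

  for (i in seq_len(length(bounds) - 1)) {
    b0 <- bounds[i]; b1 <- bounds[i + 1]
    seg_times <- grid[grid >= b0 - 1e-12 & grid <= b1 + 1e-12]
    if (length(seg_times) < 2) seg_times <- c(b0, b1)
    out <- tryCatch(
      deSolve::lsodar(y = y, times = seg_times, func = "mi_derivs",
                      parms = parms, dllname = "metroimmune",
                      initfunc = "mi_initmod", rootfunc = "mi_root",
                      nroot = 1L, rtol = rtol, atol = atol,
                      maxsteps = maxsteps),
      error = function(e) {
        stop(sprintf("integration failed in [%g, %g]: %s",
                     b0, b1, conditionMessage(e)), call. = FALSE)
      })
    istate <- attr(out, "istate")[1]
    if (!is.null(istate) && istate < 0) {
      stop(sprintf("integrator failure (istate = %d) near day %g",
                   istate, out[nrow(out), 1]))
    }
    m <- unclass(out)
    if (any(!is.finite(m))) {
      bad_t <- m[which(!is.finite(m), arr.ind = TRUE)[1, 1], 1]
      stop(sprintf("non-finite state encountered near day %g", bad_t))
    }
    reached_end <- abs(m[nrow(m), 1] - b1) <= 1e-9
    if (!reached_end || !is.null(attr(out, "troot"))) {
      # terminal root: tumor hit the overflow cap
      overflow <- TRUE
      overflow_time <- m[nrow(m), 1]
      rows <- rbind(rows, m)
      break
    }
    is_event <- nrow(ev) && any(abs(ev$time - b1) < 1e-9)
    if (is_event) {
      last <- m[nrow(m), ]
      pre_dose <- rbind(pre_dose, last)
      rows <- rbind(rows, m[-nrow(m), , drop = FALSE])
      y <- clip_state(last[-1], neg_tol)
      y[["C"]] <- y[["C"]] + ev$amount[which(abs(ev$time - b1) < 1e-9)]
      if (i == length(bounds) - 1) {
        # dose exactly at t_end: close the trajectory with the
        # post-dose state (there is no further segment to supply it)
        rows <- rbind(rows, c(b1, y))
      }
    } else {
      rows <- rbind(rows, m)
      y <- clip_state(m[nrow(m), -1], neg_tol)
    }
  }

  times_out <- rows[, 1]
  keep <- !duplicated(round(times_out, 9))
  states <- rows[keep, -1, drop = FALSE]
  times_out <- times_out[keep]
  colnames(states) <- STATE_NAMES
  states <- t(apply(states, 1, clip_state, neg_tol = neg_tol))
  colnames(states) <- STATE_NAMES

  if (!is.null(pre_dose)) {
    pre_dose <- as.data.frame(pre_dose)
    names(pre_dose) <- c("time", STATE_NAMES)
  }
  structure(list(times = unname(times_out), states = states,
                 pre_dose = pre_dose, schedule = schedule,
                 params = params, overflow = overflow,
                 overflow_time = overflow_time),
            class = "mi_trajectory")
}

clip_state <- function(y, neg_tol) {
  neg <- y < 0
  if (any(y[neg] < -neg_tol)) {
    stop("state undershoot beyond tolerance: ",
         paste(names(y)[y < -neg_tol], collapse = ", "),
         " (min ", format(min(y)), ")")
  }
  y[neg] <- 0
  y
}

#' @export
print.mi_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mi_trajectory> %s: %d time points over [%g, %g] d, %d dose(s)%s\n",
    schedule_label(x$schedule), length(x$times), min(x$times),
    max(x$times), nrow(x$schedule),
    if (x$overflow) sprintf(" [OVERFLOW at day %g]", x$overflow_time)
    else ""))
  cat(sprintf("  final state: C=%.3g T=%.4g I=%.3g X=%.3g Y=%.3g\n",
              x$states[nrow(x$states), 1], x$states[nrow(x$states), 2],
              x$states[nrow(x$states), 3], x$states[nrow(x$states), 4],
              x$states[nrow(x$states), 5]))
  invisible(x)
}

#' Tidy data frame of a simulated trajectory
#' @param x An `mi_trajectory`.
#' @param row.names,optional,... Passed for S3 compatibility (unused).
#' @return Data frame with columns time_day, C, T, I, X, Y,
#'   regimen_label.
#' @export
as.data.frame.mi_trajectory <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(time_day = x$times, x$states,
             regimen_label = schedule_label(x$schedule),
             stringsAsFactors = FALSE)
}

#' Interpolate trajectory states at arbitrary times
#' @param traj An `mi_trajectory`.
#' @param at Times within the simulated range.
#' @param var State name (default "T").
#' @return Numeric vector of interpolated values.
#' @export
trajectory_at <- function(traj, at, var = "T") {
  if (any(at < min(traj$times) - 1e-9) || any(at > max(traj$times) + 1e-9)) {
    stop("requested times outside the simulated range")
  }
  stats::approx(traj$times, traj$states[, var], xout = at, rule = 2)$y
}

#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV holds the tidy states (time_day, C, T, I, X, Y,
#' regimen_label); the sidecar records the parameter set, the schedule
#' and the overflow flag so the run is reconstructible.
#'
#' @param traj An `mi_trajectory`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_csv_atomic(as.data.frame(traj), path)
  sidecar <- list(
    params = params_to_list(traj$params),
    schedule = list(label = schedule_label(traj$schedule),
                    time = traj$schedule$time,
                    amount = traj$schedule$amount),
    overflow = traj$overflow,
    overflow_time = if (is.na(traj$overflow_time)) NULL
                    else traj$overflow_time
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Fixed-step RK4 simulation (numerical oracle)
#'
#' Integrates the same model with a classical fixed-step Runge-Kutta 4
#' scheme (compiled, with an independently transcribed right-hand side).
#' Intended as a brute-force cross-check of the adaptive solver, not for
#' production use: cost grows as `t_end / h`.
#'
#' @inheritParams simulate_tumor
#' @param h Fixed step size in days (default 1e-4).
#' @param dt_out Output resolution (must be an integer multiple of `h`).
#' @return An `mi_trajectory` (without overflow handling).
#' @export
rk4_simulate <- function(params, schedule = dose_schedule(), T0, t_end,
                         h = 1e-4, dt_out = 0.1) {
  params <- as_parameter_set(params)
  thin <- max(1L, as.integer(round(dt_out / h)))
  ev <- schedule[schedule$time <= t_end, , drop = FALSE]
  y <- c(C = 0, T = unname(T0), I = 0, X = 0, Y = 0)
  if (nrow(ev) && ev$time[1] == 0) y[["C"]] <- y[["C"]] + ev$amount[1]
  bounds <- sort(unique(c(0, ev$time[ev$time > 0], t_end)))
  p <- as.numeric(unclass(params))
  all_t <- NULL; all_s <- NULL
  for (i in seq_len(length(bounds) - 1)) {
    b0 <- bounds[i]; b1 <- bounds[i + 1]
    nsteps <- as.integer(round((b1 - b0) / h))
    nrec <- nsteps %/% thin + 1L + as.integer(nsteps %% thin != 0)
    res <- .C("mi_rk4", p = as.double(p), y = as.double(y),
              h = as.double(h), nsteps = nsteps, thin = as.integer(thin),
              out = double(5L * nrec))
    states <- matrix(res$out, ncol = 5, byrow = TRUE)
    rec_steps <- unique(c(seq(0L, nsteps, by = thin), nsteps))
    tt <- b0 + rec_steps * h
    if (i > 1) { states <- states[-1, , drop = FALSE]; tt <- tt[-1] }
    all_t <- c(all_t, tt); all_s <- rbind(all_s, states)
    y <- res$y
    names(y) <- STATE_NAMES
    is_event <- nrow(ev) && any(abs(ev$time - b1) < 1e-9)
    if (is_event) {
      y[["C"]] <- y[["C"]] + ev$amount[which(abs(ev$time - b1) < 1e-9)]
      all_s[nrow(all_s), 1] <- y[["C"]]  # store post-dose, as in simulate_tumor
    }
  }
  colnames(all_s) <- STATE_NAMES
  structure(list(times = all_t, states = all_s, pre_dose = NULL,
                 schedule = schedule, params = params,
                 overflow = FALSE, overflow_time = NA_real_),
            class = "mi_trajectory")
}

write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
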