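# Post-simulation analyses: immune-peak timing, normalized mean growth
# curves, escape classification, kill attribution, regimen predictions.

#' Time of the immune-indicator peak
#'
#' Finds the global maximum of the aggregate immune indicator I(t)
#' within a window, refining the discrete argmax by parabolic
#' interpolation through its two grid neighbors (reported peak times
#' are day-resolution; refinement avoids grid artifacts). Ties break
#' toward the earliest time; a maximum on the window boundary is
#' flagged and not refined.
#'
#' @param traj An `mi_trajectory`.
#' @param window `(t0, t1)` in days; defaults to the full simulated
#'   horizon.
#' @return List with `peak_day`, `peak_value` and `at_boundary`.
#' @export
peak_immune_time <- function(traj, window = range(traj$times)) {
  if (window[1] < min(traj$times) - 1e-9 ||
      window[2] > max(traj$times) + 1e-9 || window[1] >= window[2]) {
    stop("window must lie within the simulated horizon")
  }
  in_win <- traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9
  tt <- traj$times[in_win]
  ii <- traj$states[in_win, "I"]
  k <- which.max(ii)  # earliest index on ties
  at_boundary <- k == 1L || k == length(ii)
  peak_day <- tt[k]
  peak_value <- ii[k]
  if (!at_boundary) {
    # parabola through (t_{k-1}, I_{k-1}), (t_k, I_k), (t_{k+1}, I_{k+1})
    x <- tt[(k - 1):(k + 1)]; y <- ii[(k - 1):(k + 1)]
    d1 <- (y[2] - y[1]) / (x[2] - x[1])
    d2 <- (y[3] - y[2]) / (x[3] - x[2])
    curv <- (d2 - d1) / (x[3] - x[1]) * 2
    if (curv < 0) {
      vertex <- (x[1] + x[2]) / 2 - d1 / curv
      if (vertex >= x[1] && vertex <= x[3]) {
        peak_day <- vertex
        peak_value <- y[2] - curv / 2 * ((x[2] - vertex))^2
      }
    }
  }
  list(peak_day = unname(peak_day), peak_value = unname(peak_value),
       at_boundary = at_boundary)
}

#' Normalize growth curves to 100 at baseline and average per arm
#'
#' Each subject's curve is scaled so its first point equals 100, then
#' curves are averaged arithmetically across subjects at each day.
#' Days without full coverage are averaged over the available subjects,
#' with the count reported.
#'
#' @param data A measurement table (see [generate_cohort()]), or a data
#'   frame with columns `subject_id`, `day` and `volume_mm3` (and `arm`
#'   when `arm` is used to filter).
#' @param arm Optional arm label to restrict to.
#' @return An `mi_arm_summary`: data frame with `day`,
#'   `mean_normalized` and `n_subjects`; attributes `arm_label` and
#'   `n_subjects` (total), `n_escaped` is filled by
#'   [predict_regimens()] style analyses.
#' @export
normalize_and_average <- function(data, arm = NULL) {
  if (!is.null(arm)) {
    data <- data[data$arm == arm, , drop = FALSE]
    if (!nrow(data)) stop("no rows for arm '", arm, "'")
  }
  if (!nrow(data)) stop("empty table")
  per_subject <- lapply(split(data, data$subject_id), function(d) {
    d <- d[order(d$day), ]
    if (!is.finite(d$volume_mm3[1]) || d$volume_mm3[1] <= 0) {
      stop("subject ", d$subject_id[1], ": baseline volume must be > 0")
    }
    data.frame(day = d$day,
               normalized = d$volume_mm3 / d$volume_mm3[1] * 100)
  })
  pooled <- do.call(rbind, per_subject)
  agg <- stats::aggregate(normalized ~ day, data = pooled, FUN = mean)
  cnt <- stats::aggregate(normalized ~ day, data = pooled, FUN = length)
  out <- data.frame(day = agg$day, mean_normalized = agg$normalized,
                    n_subjects = cnt$normalized)
  out <- out[order(out$day), ]
  rownames(out) <- NULL
  structure(out, arm_label = if (is.null(arm)) "all" else arm,
            n_subjects = length(per_subject),
            class = c("mi_arm_summary", "data.frame"))
}

#' Classify a tumor growth curve as escaped, suppressed, regressing or
#' progressing
#'
#' A curve has escaped when its volume attains an interior minimum and
#' later exceeds `rebound_factor` times that minimum; the rebound day
#' is the first such crossing. Without a rebound, the curve is
#' suppressed when the final volume is at most `suppression_factor`
#' times baseline; otherwise it is regressing (net shrinkage) or
#' progressing (net growth — e.g. untreated exponential curves, which
#' have no interior minimum and so can never "escape"). The rule
#' thresholds are recorded in the result.
#'
#' @param volumes Tumor volumes (> 0), or an `mi_trajectory`.
#' @param days Measurement days (same length as `volumes`; taken from
#'   the trajectory when one is given).
#' @param rebound_factor Escape threshold on volume / interior minimum
#'   (default 2.0).
#' @param suppression_factor Suppression threshold on final volume /
#'   baseline (default 0.5).
#' @return List with `status` (one of `"escaped"`, `"suppressed"`,
#'   `"regressing"`, `"progressing"`), `rebound_day` (`NA` unless
#'   escaped), `min_day`, and `rules`.
#' @export
classify_escape <- function(volumes, days = NULL, rebound_factor = 2,
                            suppression_factor = 0.5) {
  if (inherits(volumes, "mi_trajectory")) {
    days <- volumes$times
    volumes <- volumes$states[, "T"]
  }
  if (length(volumes) < 3) stop("curve must span at least 3 time points")
  if (length(days) != length(volumes)) stop("days/volumes length mismatch")
  ord <- order(days)
  days <- days[ord]; volumes <- volumes[ord]

  im <- which.min(volumes)  # earliest global minimum on ties
  vmin <- volumes[im]
  status <- NULL; rebound_day <- NA_real_
  if (im > 1L && im < length(volumes)) {
    later <- seq(im + 1L, length(volumes))
    crossing <- later[volumes[later] >= rebound_factor * vmin]
    if (length(crossing)) {
      status <- "escaped"
      rebound_day <- days[crossing[1]]
    }
  }
  if (is.null(status)) {
    baseline <- volumes[1]
    final <- volumes[length(volumes)]
    status <- if (final <= suppression_factor * baseline) "suppressed"
              else if (final < baseline) "regressing"
              else "progressing"
  }
  list(status = status, rebound_day = rebound_day, min_day = days[im],
       rules = c(rebound_factor = rebound_factor,
                 suppression_factor = suppression_factor))
}

#' Attribute tumor cell kill to drug versus immune mechanisms
#'
#' Integrates the two kill terms of the tumor equation along a
#' simulated trajectory over a horizon: drug kill `kb*C*T/(kc+T)` and
#' immune kill `kd*T*I` (both mm^3 of tumor removed), plus the growth
#' integral `ka*T`, using trapezoidal quadrature on the trajectory's
#' own output grid. Because dose events change only the drug state C,
#' the tumor volume is continuous across doses and the mass balance
#' `T(t1) - T(t0) = growth - drug_kill - immune_kill` holds to
#' quadrature accuracy over any horizon.
#'
#' @param traj An `mi_trajectory`.
#' @param horizon `(t0, t1)` in days within the trajectory; default the
#'   full horizon.
#' @return List with `drug_kill`, `immune_kill`, `growth` and
#'   `horizon`.
#' @export
attribute_kill <- function(traj, horizon = range(traj$times)) {
  if (horizon[1] < min(traj$times) - 1e-9 ||
      horizon[2] > max(traj$times) + 1e-9 || horizon[1] >= horizon[2]) {
    stop("horizon must lie within the simulated trajectory")
  }
  sel <- traj$times >= horizon[1] - 1e-9 & traj$times <= horizon[2] + 1e-9
  tt <- traj$times[sel]
  S <- traj$states[sel, , drop = FALSE]
  p <- as.list(unclass(traj$params))
  rate_of <- function(C, T, I) {
    cbind(drug = p$kb * C * T / (p$kc + T),
          imm = p$kd * T * I,
          growth = p$ka * T)
  }
  left <- rate_of(S[, "C"], S[, "T"], S[, "I"])
  # C jumps at dose times (stored values are post-dose); use the
  # pre-dose limit for the RIGHT endpoint of the interval ending at a
  # dose, so the trapezoid never straddles the discontinuity
  right <- left
  if (!is.null(traj$pre_dose)) {
    for (j in seq_len(nrow(traj$pre_dose))) {
      i <- which(abs(tt - traj$pre_dose$time[j]) < 1e-9)
      if (length(i) == 1 && i > 1) {
        right[i, ] <- rate_of(traj$pre_dose$C[j], traj$pre_dose$T[j],
                              traj$pre_dose$I[j])
      }
    }
  }
  n <- length(tt)
  w <- diff(tt)
  integ <- colSums(w * (left[-n, , drop = FALSE] +
                        right[-1, , drop = FALSE]) / 2)
  list(drug_kill = unname(integ["drug"]),
       immune_kill = unname(integ["imm"]),
       growth = unname(integ["growth"]),
       horizon = horizon)
}

#' Predict outcomes across dosing regimens
#'
#' Simulates each regimen from each initial volume on a grid, then
#' classifies escape, attributes kill, and extracts the immune peak for
#' every run. Deterministic (no measurement noise).
#'
#' @param params An `mi_params`.
#' @param regimens Character vector of registry names, or a named list
#'   of `mi_regimen_spec`.
#' @param T0_grid Initial tumor volumes (mm^3).
#' @param t_end Horizon in days (default 45).
#' @param dt Output resolution (default 0.05 d, fine enough for
#'   quadrature-accurate kill attribution).
#' @param ... Passed to [classify_escape()] (rule thresholds).
#' @return An `mi_prediction`: data frame with one row per
#'   (regimen, T0): final/minimum volume, escape status and rebound
#'   day, drug and immune kill, immune peak day; attribute
#'   `trajectories` holds the underlying `mi_trajectory` objects,
#'   attribute `summaries` the per-regimen normalized mean curves.
#' @export
predict_regimens <- function(params, regimens, T0_grid = c(300, 650, 1000),
                             t_end = 45, dt = 0.05, ...) {
  params <- as_parameter_set(params)
  if (is.character(regimens)) {
    regimens <- stats::setNames(lapply(regimens, regimen), regimens)
  }
  rows <- list(); trajs <- list(); curves <- list()
  for (nm in names(regimens)) {
    sched <- build_schedule(regimens[[nm]], t_end)
    for (T0 in T0_grid) {
      traj <- simulate_tumor(params, sched, T0 = T0, t_end = t_end, dt = dt)
      cls <- classify_escape(traj, ...)
      kill <- attribute_kill(traj)
      pk <- peak_immune_time(traj)
      key <- sprintf("%s@%g", nm, T0)
      trajs[[key]] <- traj
      rows[[key]] <- data.frame(
        regimen = nm, T0 = T0,
        final_volume = traj$states[nrow(traj$states), "T"],
        min_volume = min(traj$states[, "T"]),
        status = cls$status, rebound_day = cls$rebound_day,
        escaped = cls$status == "escaped" || traj$overflow,
        overflow = traj$overflow,
        drug_kill = kill$drug_kill, immune_kill = kill$immune_kill,
        immune_peak_day = pk$peak_day,
        stringsAsFactors = FALSE)
      curves[[key]] <- data.frame(
        subject_id = key, arm = nm, day = traj$times,
        volume_mm3 = pmax(traj$states[, "T"], 1e-12))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pooled <- do.call(rbind, curves)
  summaries <- lapply(stats::setNames(names(regimens), names(regimens)),
                      function(nm) normalize_and_average(pooled, arm = nm))
  structure(out, trajectories = trajs, summaries = summaries,
            params = params,
            class = c("mi_prediction", "data.frame"))
}

#' Escape counts per regimen from a prediction table
#' @param pred An `mi_prediction`.
#' @return Data frame with `regimen`, `n_runs`, `n_escaped`.
#' @export
escape_counts <- function(pred) {
  agg <- stats::aggregate(escaped ~ regimen, data = as.data.frame(pred),
                          FUN = sum)
  n <- stats::aggregate(escaped ~ regimen, data = as.data.frame(pred),
                        FUN = length)
  data.frame(regimen = agg$regimen, n_runs = n$escaped,
             n_escaped = agg$escaped)
}
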