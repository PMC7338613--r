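# Dosing regimens: impulsive bolus schedules in days.
#
# Doses are nondimensional. The reference experimental dose (140 mg/kg)
# maps to amount D = 1 by default; other doses scale proportionally, so
# 210 mg/kg -> 1.5 * D. Only the dose ratio is constrained by the
# nondimensionalization.

REFERENCE_DOSE_MGKG <- 140

#' Create a dose schedule
#'
#' An ordered sequence of impulsive dose events. Each event instantly
#' adds `amount` to the drug concentration C at `time` (days); the
#' administration rate u(t) is zero elsewhere, reflecting the fast
#' injection/activation time scale relative to tumor-immune dynamics.
#'
#' @param times Strictly increasing event days (>= 0, finite).
#' @param amounts Positive nondimensional bolus amounts, recycled to
#'   `length(times)`.
#' @param label Regimen name carried through simulations and outputs.
#' @return A data frame of class `mi_schedule` with columns `time` and
#'   `amount`; zero rows encode an untreated regimen.
#' @export
dose_schedule <- function(times = numeric(0), amounts = numeric(0),
                          label = "custom") {
  times <- as.numeric(times)
  if (length(times)) {
    amounts <- rep_len(as.numeric(amounts), length(times))
    if (any(!is.finite(times)) || any(times < 0)) {
      stop("dose times must be finite and >= 0")
    }
    if (is.unsorted(times, strictly = TRUE)) {
      stop("dose times must be strictly increasing")
    }
    if (any(!is.finite(amounts)) || any(amounts <= 0)) {
      stop("dose amounts must be finite and > 0")
    }
  } else {
    amounts <- numeric(0)
  }
  structure(data.frame(time = times, amount = amounts),
            label = label, class = c("mi_schedule", "data.frame"))
}

#' @export
print.mi_schedule <- function(x, ...) {
  cat(sprintf("<mi_schedule> %s: %d dose(s)\n", attr(x, "label"), nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

schedule_label <- function(schedule) {
  lbl <- attr(schedule, "label")
  if (is.null(lbl)) "custom" else lbl
}

#' Describe a dosing regimen
#'
#' @param name Regimen label.
#' @param dose_mgkg Dose per administration in mg/kg; converted to a
#'   nondimensional amount as `dose_mgkg / 140 * ref_amount`.
#' @param intervals Inter-dose intervals in days. A single value means a
#'   fixed interval; a vector (e.g. `c(6, 9)`) cycles. Ignored when
#'   `n_doses` is 0 or 1.
#' @param n_doses Number of doses, or `NULL` to repeat until the horizon
#'   passed to [build_schedule()]. Use 0 for an untreated regimen.
#' @return A list of class `mi_regimen_spec`.
#' @export
regimen_spec <- function(name, dose_mgkg = 140, intervals = 6,
                         n_doses = NULL) {
  if (!is.null(n_doses)) {
    n_doses <- as.integer(n_doses)
    if (n_doses < 0) stop("n_doses must be >= 0")
  }
  if (is.null(n_doses) || n_doses > 1) {
    if (!length(intervals)) stop("interval list must be non-empty")
    if (any(!is.finite(intervals)) || any(intervals <= 0)) {
      stop("intervals must be finite and > 0")
    }
  }
  if (!is.finite(dose_mgkg) || dose_mgkg <= 0) stop("dose must be > 0")
  structure(list(name = name, dose_mgkg = dose_mgkg,
                 intervals = as.numeric(intervals), n_doses = n_doses),
            class = "mi_regimen_spec")
}

#' @export
print.mi_regimen_spec <- function(x, ...) {
  cat(sprintf("<mi_regimen_spec> %s: %g mg/kg, intervals [%s], %s doses\n",
              x$name, x$dose_mgkg,
              paste(x$intervals, collapse = ", "),
              if (is.null(x$n_doses)) "until horizon" else x$n_doses))
  invisible(x)
}

#' Build a dose schedule from a regimen description
#'
#' The first dose is always on day 0. Fixed-interval regimens repeat
#' until `n_doses` is reached or, when `n_doses` is `NULL`, while event
#' times stay `<= t_end`. Interval lists cycle (`c(6, 9)` gives breaks
#' 6, 9, 6, 9, ...).
#'
#' @param spec An `mi_regimen_spec`, or a registry name (see
#'   [list_regimens()]).
#' @param t_end Horizon in days (>= 0); caps open-ended regimens.
#' @param ref_amount Nondimensional amount corresponding to the
#'   reference 140 mg/kg dose (default 1).
#' @return An `mi_schedule`.
#' @export
build_schedule <- function(spec, t_end, ref_amount = 1) {
  if (is.character(spec)) spec <- regimen(spec)
  if (!inherits(spec, "mi_regimen_spec")) {
    stop("spec must be an mi_regimen_spec or a registry name")
  }
  if (!is.finite(t_end) || t_end < 0) stop("t_end must be finite and >= 0")
  if (!is.null(spec$n_doses) && spec$n_doses == 0) {
    return(dose_schedule(label = spec$name))
  }
  amount <- spec$dose_mgkg / REFERENCE_DOSE_MGKG * ref_amount
  if (!is.null(spec$n_doses)) {
    n <- spec$n_doses
    times <- cumsum(c(0, rep_len(spec$intervals, n - 1)))
  } else {
    times <- 0
    k <- 0L
    repeat {
      nxt <- times[length(times)] +
        spec$intervals[k %% length(spec$intervals) + 1L]
      if (nxt > t_end) break
      times <- c(times, nxt)
      k <- k + 1L
    }
  }
  dose_schedule(times, rep(amount, length(times)), label = spec$name)
}

# Registry of the named regimens from the GL261 experiments plus the two
# prediction-only schedules. Doses are 140 mg/kg unless stated.
regimen_registry <- function() {
  list(
    "untreated"        = regimen_spec("untreated", n_doses = 0),
    "1-CPA"            = regimen_spec("1-CPA", n_doses = 1),
    "2-CPA"            = regimen_spec("2-CPA", intervals = 6, n_doses = 2),
    "3-CPA"            = regimen_spec("3-CPA", intervals = 6, n_doses = 3),
    "CPA/6-days"       = regimen_spec("CPA/6-days", intervals = 6),
    "CPA/9-days"       = regimen_spec("CPA/9-days", intervals = 9),
    "CPA/12-days"      = regimen_spec("CPA/12-days", intervals = 12),
    "CPA/6-9-days"     = regimen_spec("CPA/6-9-days", intervals = c(6, 9)),
    "CPA/9-days(210)"  = regimen_spec("CPA/9-days(210)", dose_mgkg = 210,
                                      intervals = 9),
    "CPA/9-6-days"     = regimen_spec("CPA/9-6-days", intervals = c(9, 6)),
    "CPA/7.5-days"     = regimen_spec("CPA/7.5-days", intervals = 7.5)
  )
}

#' Look up a built-in regimen by name
#' @param name One of the names in [list_regimens()].
#' @return An `mi_regimen_spec`.
#' @export
regimen <- function(name) {
  reg <- regimen_registry()
  if (!name %in% names(reg)) {
    stop("unknown regimen '", name, "'; known: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Names of the built-in dosing regimens
#' @return Character vector of registry names.
#' @export
list_regimens <- function() names(regimen_registry())

# The experimental arms (those with reported growth-curve data), used as
# the default cohort panel; the two trailing registry entries are
# prediction-only schedules.
experimental_arm_names <- function() {
  c("untreated", "1-CPA", "2-CPA", "3-CPA", "CPA/6-days",
    "CPA/6-9-days", "CPA/9-days", "CPA/9-days(210)", "CPA/12-days")
}

#' Total administered amount over a horizon
#' @param schedule An `mi_schedule`.
#' @param t_end Horizon (inclusive) in days.
#' @return Sum of amounts of events with `time <= t_end`.
#' @export
total_dose <- function(schedule, t_end = Inf) {
  sum(schedule$amount[schedule$time <= t_end])
}
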