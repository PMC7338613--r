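#' @useDynLib metroimmune, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# canonical parameter order used everywhere (R, C, CSV, JSON)
PAR_NAMES <- c("k1", "k2", "ka", "kb", "kc", "kd", "ke", "kf",
               "kg", "kh", "ki", "kj", "kk", "kl", "km")

PAR_DESCRIPTIONS <- c(
  k1 = "maximum drug clearance rate (nondim conc/day)",
  k2 = "drug clearance half-saturation (nondim conc)",
  ka = "tumor exponential growth rate (1/day)",
  kb = "drug cytotoxicity on tumor (nondim)",
  kc = "tumor-kill saturation volume (mm^3)",
  kd = "immune-mediated tumor kill rate (nondim)",
  ke = "net immune exhaustion by tumor (nondim)",
  kf = "drug toxicity on the immune compartment (nondim)",
  kg = "suppression of immune indicator by Y (nondim)",
  kh = "natural immune decay (1/day)",
  ki = "drug threshold for X-recruitment saturation (nondim conc)",
  kj = "X decay rate (1/day)",
  kk = "X inactivation by Y (nondim)",
  kl = "drug threshold damping Y production (nondim conc)",
  km = "Y clearance by drug (nondim)"
)

#' Create a model parameter set
#'
#' Bundles the fifteen positive rate constants of the tumor-immune-drug
#' model into a validated, named numeric vector of class `mi_params`.
#' The model is nondimensionalized: only `ka`, `kh`, `kj` (1/day), `kc`
#' (mm^3) and the drug thresholds carry interpretable scales.
#'
#' @param k1,k2 Michaelis-Menten drug clearance: maximum rate and
#'   half-saturation concentration.
#' @param ka Tumor exponential growth rate (1/day).
#' @param kb,kc Drug-mediated tumor kill rate and its saturation volume
#'   (mm^3); the kill term is `kb*C*T/(kc + T)`.
#' @param kd Immune-mediated tumor kill rate.
#' @param ke Net exhaustion of the immune indicator by tumor contact.
#' @param kf Drug toxicity on the immune compartment.
#' @param kg Suppression of the immune indicator by the suppressor Y.
#' @param kh Natural immune decay rate (1/day).
#' @param ki Drug threshold above which X-recruitment saturates.
#' @param kj,kk Decay of the immunostimulatory intermediate X and its
#'   inactivation by Y.
#' @param kl Drug threshold damping production of the suppressor Y.
#' @param km Clearance of Y by the drug.
#' @return A named numeric vector of class `mi_params`.
#' @export
parameter_set <- function(k1, k2, ka, kb, kc, kd, ke, kf, kg, kh,
                          ki, kj, kk, kl, km) {
  p <- c(k1 = k1, k2 = k2, ka = ka, kb = kb, kc = kc, kd = kd,
         ke = ke, kf = kf, kg = kg, kh = kh, ki = ki, kj = kj,
         kk = kk, kl = kl, km = km)
  validate_params(p)
}

#' Coerce a named vector or list to a parameter set
#'
#' @param x A named numeric vector or list containing all fifteen rate
#'   constants (extra names are an error).
#' @return An `mi_params` object.
#' @export
as_parameter_set <- function(x) {
  if (inherits(x, "mi_params")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) || !setequal(names(x), PAR_NAMES)) {
    missing <- setdiff(PAR_NAMES, names(x))
    extra <- setdiff(names(x), PAR_NAMES)
    stop("parameter set must have exactly the names ",
         paste(PAR_NAMES, collapse = ", "),
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(extra, collapse = ", ")))
  }
  validate_params(x[PAR_NAMES])
}

validate_params <- function(p) {
  p <- as.numeric(p[PAR_NAMES])
  names(p) <- PAR_NAMES
  bad <- !is.finite(p) | p <= 0
  if (any(bad)) {
    stop("parameters must be strictly positive and finite; offending: ",
         paste(PAR_NAMES[bad], collapse = ", "))
  }
  structure(p, class = "mi_params")
}

#' @export
print.mi_params <- function(x, ...) {
  cat("<mi_params> 15 rate constants of the tumor-immune-drug model\n")
  print(format(unclass(x), digits = 4), quote = FALSE)
  invisible(x)
}

#' @export
format.mi_params <- function(x, ...) format(unclass(x), ...)

#' Serialize a parameter set to a list (for YAML/JSON round-trips)
#' @param x An `mi_params` object.
#' @return A named list of 15 numbers, in canonical order.
#' @export
params_to_list <- function(x) {
  x <- as_parameter_set(x)
  as.list(unclass(x))
}

#' Reference "truth" parameter set shipped with the package
#'
#' A fixture parameter set chosen so that simulated cohorts reproduce the
#' qualitative regimen ordering observed in the GL261 metronomic
#' cyclophosphamide experiments: untreated tumors grow exponentially,
#' every-6-day dosing at the reference dose yields sustained regression,
#' every-12-day dosing escapes early, and the aggregate immune indicator
#' peaks roughly one inter-dose interval later for each added dose.
#' It is a synthetic reference point for testing and simulation, not a
#' fitted estimate from experimental data.
#'
#' @return An `mi_params` object.
#' @export
default_truth_params <- function() {
  parameter_set(
    k1 = 0.50, k2 = 0.30,
    ka = 0.18, kb = 300, kc = 100, kd = 0.25,
    ke = 2e-4, kf = 2.0, kg = 0.005, kh = 0.05,
    ki = 0.10, kj = 0.08, kk = 0.02, kl = 0.30, km = 1.5
  )
}

#' Model right-hand side (reference R implementation)
#'
#' Evaluates the instantaneous derivatives of the five model states
#' (C drug, T tumor, I immune indicator, X immunostimulatory
#' intermediate, Y immunosuppressive intermediate). This plain-R
#' transcription is the readable reference; simulation uses a compiled
#' equivalent which is tested against it.
#'
#' @param state Named numeric vector `c(C=, T=, I=, X=, Y=)`, all
#'   components nonnegative.
#' @param params An `mi_params` object.
#' @param u Drug administration rate (>= 0); zero between boluses.
#' @param neg_tol How far below zero a state component may be (numerical
#'   noise) before it is an error.
#' @return Named numeric vector of derivatives `(dC, dT, dI, dX, dY)`.
#' @export
model_rhs <- function(state, params, u = 0, neg_tol = 1e-9) {
  params <- as_parameter_set(params)
  state <- unlist(state)
  if (is.null(names(state)) || !setequal(names(state), STATE_NAMES)) {
    stop("state must have names ", paste(STATE_NAMES, collapse = ", "))
  }
  state <- state[STATE_NAMES]
  if (any(!is.finite(state))) {
    stop("non-finite state component: ",
         paste(STATE_NAMES[!is.finite(state)], collapse = ", "))
  }
  if (any(state < -neg_tol)) {
    stop("negative state component beyond tolerance: ",
         paste(STATE_NAMES[state < -neg_tol], collapse = ", "))
  }
  if (!is.finite(u) || u < 0) stop("u must be finite and >= 0")
  p <- as.list(unclass(params))
  C <- state[["C"]]; T <- state[["T"]]; I <- state[["I"]]
  X <- state[["X"]]; Y <- state[["Y"]]
  with(p, c(
    C = u - k1 * C / (k2 + C),
    T = ka * T - kb * C * T / (kc + T) - kd * T * I,
    I = X - ke * T * I - kf * C * I - kg * Y * I - kh * I,
    X = C / (1 + C / ki) - kj * X - kk * X * Y,
    Y = I / (1 + C / kl) - km * Y * C
  ))
}

STATE_NAMES <- c("C", "T", "I", "X", "Y")
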