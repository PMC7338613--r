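# Shared fixtures and independent oracles, built in code at test time.

FIXTURE <- default_truth_params()

# log-uniform parameter draw centered on the fixture values; `spread` is
# the half-width in decades. Used for property-style tests.
draw_params <- function(spread = 1) {
  base <- log10(unclass(FIXTURE))
  as_parameter_set(10^(base + stats::runif(15, -spread, spread)))
}

# A small two-arm cohort for calibration plumbing tests.
tiny_cohort <- function(seed = 1, noise = 0, n = 4,
                        arms = c("untreated" = n, "CPA/6-days" = n)) {
  generate_cohort(cohort_spec(
    arms = arms, n_per_arm = n, noise_sd_log = noise, seed = seed,
    measurement_days = seq(0, 24, by = 6)))
}

# Independent plain-R RK4 stepper over the exported model_rhs(), used to
# cross-check the compiled fixed-step integrator on short horizons.
r_rk4 <- function(params, state, h, nsteps, u = 0) {
  for (s in seq_len(nsteps)) {
    k1 <- model_rhs(state, params, u)
    k2 <- model_rhs(state + h / 2 * k1, params, u)
    k3 <- model_rhs(state + h / 2 * k2, params, u)
    k4 <- model_rhs(state + h * k3, params, u)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  state
}

# Hand-rolled trajectory container for analysis tests that inject
# synthetic state curves directly.
fake_trajectory <- function(times, I = NULL, T = NULL,
                            params = FIXTURE) {
  n <- length(times)
  states <- cbind(C = rep(0, n),
                  T = if (is.null(T)) rep(1, n) else T,
                  I = if (is.null(I)) rep(0, n) else I,
                  X = rep(0, n), Y = rep(0, n))
  structure(list(times = times, states = states, pre_dose = NULL,
                 schedule = dose_schedule(label = "synthetic"),
                 params = params, overflow = FALSE,
                 overflow_time = NA_real_),
            class = "mi_trajectory")
}

# Relative deviation with an absolute guard for near-zero states.
rel_dev <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(b), floor))
}
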