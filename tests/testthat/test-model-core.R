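test_that("parameter sets validate, print and round-trip", {
  p <- FIXTURE
  expect_s3_class(p, "mi_params")
  expect_error(parameter_set(k1 = -1, k2 = 1, ka = 1, kb = 1, kc = 1,
                             kd = 1, ke = 1, kf = 1, kg = 1, kh = 1,
                             ki = 1, kj = 1, kk = 1, kl = 1, km = 1),
               "strictly positive")
  expect_error(as_parameter_set(c(unclass(p)[-1], bogus = 1)), "k1")

  # lossless serialization through the structured sidecar format
  json <- tempfile(fileext = ".json")
  jsonlite::write_json(params_to_list(p), json, auto_unbox = TRUE,
                       digits = NA)
  back <- as_parameter_set(jsonlite::read_json(json,
                                               simplifyVector = TRUE))
  expect_equal(unclass(back), unclass(p), tolerance = 1e-12)
  # and through YAML, the config format
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(params_to_list(p), yml)
  expect_equal(unclass(as_parameter_set(yaml::read_yaml(yml))),
               unclass(p), tolerance = 1e-12)
})

test_that("model right-hand side matches hand-derived values", {
  ones <- as_parameter_set(stats::setNames(rep(1, 15),
    c("k1", "k2", "ka", "kb", "kc", "kd", "ke", "kf", "kg", "kh",
      "ki", "kj", "kk", "kl", "km")))
  d <- model_rhs(c(C = 1, T = 1, I = 1, X = 1, Y = 1), ones)
  expect_equal(unname(d), c(-0.5, -0.5, -3, -1.5, -0.5))

  # tumor-only state: only exponential growth survives
  set.seed(41)
  for (i in 1:20) {
    p <- draw_params()
    d0 <- model_rhs(c(C = 0, T = 0, I = 0, X = 0, Y = 0), p)
    expect_equal(unname(d0), rep(0, 5))  # origin is an equilibrium
    dT <- model_rhs(c(C = 0, T = 700, I = 0, X = 0, Y = 0), p)
    expect_equal(unname(dT), c(0, p[["ka"]] * 700, 0, 0, 0))
  }

  expect_error(model_rhs(c(C = NaN, T = 1, I = 1, X = 1, Y = 1), ones),
               "non-finite state component: C")
  expect_error(model_rhs(c(C = 0, T = -1, I = 0, X = 0, Y = 0), ones),
               "negative state component.*T")
  expect_error(model_rhs(c(C = 0, T = 1, I = 0, X = 0, Y = 0), ones,
                         u = -1), "u must be")
})

test_that("positivity is preserved at the state-space boundary", {
  # each state's derivative is nonnegative where that state is zero,
  # so trajectories cannot analytically cross into negative territory
  set.seed(42)
  for (i in 1:50) {
    p <- draw_params()
    st <- stats::runif(5, 0, 2) * c(1, 500, 1, 1, 1)
    names(st) <- c("C", "T", "I", "X", "Y")
    j <- sample(5, 1)
    st[j] <- 0
    expect_gte(model_rhs(st, p)[j], 0)
  }
})

test_that("no-drug simulation matches the exponential closed form", {
  tr <- simulate_tumor(FIXTURE, dose_schedule(label = "untreated"),
                       T0 = 500, t_end = 10)
  expected <- 500 * exp(FIXTURE[["ka"]] * tr$times)
  expect_lt(max(abs(tr$states[, "T"] - expected) / expected), 1e-6)
  expect_equal(max(abs(tr$states[, c("C", "I", "X", "Y")])), 0)
})

test_that("trajectory structure honors the dosing contract", {
  sch <- build_schedule("3-CPA", 30)
  tr <- simulate_tumor(FIXTURE, sch, T0 = 800, t_end = 20)
  expect_false(is.unsorted(tr$times, strictly = TRUE))
  # state at time zero is the initial condition plus the day-0 bolus
  expect_equal(unname(tr$states[1, ]), c(1, 800, 0, 0, 0))
  expect_true(all(tr$states >= 0))
  # pre-dose limits recorded for each event
  expect_equal(tr$pre_dose$time, c(0, 6, 12))
  i6 <- which(abs(tr$times - 6) < 1e-9)
  expect_equal(unname(tr$states[i6, "C"] - tr$pre_dose$C[2]), 1)
  # tidy export
  df <- as.data.frame(tr)
  expect_named(df, c("time_day", "C", "T", "I", "X", "Y",
                     "regimen_label"))
  expect_equal(unique(df$regimen_label), "3-CPA")
})

test_that("adaptive solver agrees with independent RK4 oracles", {
  # compiled fixed-step RK4 vs plain-R RK4 over the exported rhs
  y1 <- rk4_simulate(FIXTURE, build_schedule("1-CPA", 10), T0 = 600,
                     t_end = 1, h = 1e-3, dt_out = 1)
  y0 <- c(C = 1, T = 600, I = 0, X = 0, Y = 0)
  y2 <- r_rk4(FIXTURE, y0, h = 1e-3, nsteps = 1000)
  expect_lt(rel_dev(y1$states[nrow(y1$states), ], y2), 1e-9)

  # adaptive vs fixed-step across a dosed trajectory
  sch <- build_schedule("3-CPA", 20)
  ta <- simulate_tumor(FIXTURE, sch, T0 = 900, t_end = 20, dt = 0.1)
  tf <- rk4_simulate(FIXTURE, sch, T0 = 900, t_end = 20, h = 1e-4,
                     dt_out = 0.1)
  expect_equal(ta$times, tf$times, tolerance = 1e-9)
  expect_lt(rel_dev(ta$states, tf$states), 1e-4)
})

test_that("drug clearance shows zero-order to first-order transition", {
  # C >> k2: clearance ~ constant k1; C << k2: exponential at k1/k2
  p <- as_parameter_set(c(k1 = 0.3, k2 = 0.01, ka = 1e-4, kb = 1e-4,
                          kc = 100, kd = 1e-4, ke = 1e-4, kf = 1e-4,
                          kg = 1e-4, kh = 1e-4, ki = 1e4, kj = 1e-4,
                          kk = 1e-4, kl = 1e4, km = 1e-4))
  tr <- simulate_tumor(p, build_schedule("1-CPA", 10), T0 = 1e-3,
                       t_end = 6, dt = 0.01, cap = 1e8)
  C <- tr$states[, "C"]; tt <- tr$times
  early <- (C[2] - C[1]) / (tt[2] - tt[1])
  expect_equal(early, -p[["k1"]], tolerance = 0.02)
  late <- C > 1e-8 & C < 1e-4
  rate <- -diff(log(C[late])) / diff(tt[late])
  expect_equal(mean(rate), p[["k1"]] / p[["k2"]], tolerance = 0.01)
})

test_that("PK is additive in simultaneous boluses", {
  # two half-doses a nanosecond apart equal one full dose (tumor and
  # immune feedback on C is absent by model structure; couplings
  # zeroed anyway per the superposition contract)
  p <- unclass(FIXTURE)
  p[c("kb", "kd", "kf", "km")] <- 1e-12
  p <- as_parameter_set(p)
  one <- simulate_tumor(p, dose_schedule(0, 1, "full"), T0 = 500,
                        t_end = 10, dt = 0.1)
  half <- simulate_tumor(p, dose_schedule(c(0, 1e-9), c(0.5, 0.5),
                                          "split"), T0 = 500,
                         t_end = 10, dt = 0.1)
  common <- intersect(round(one$times, 9), round(half$times, 9))
  common <- common[common > 1e-6]
  expect_lt(max(abs(trajectory_at(one, common, "C") -
                    trajectory_at(half, common, "C"))), 1e-7)
})

test_that("tumor overflow terminates early and is flagged", {
  fast <- unclass(FIXTURE)
  fast["ka"] <- 2
  tr <- simulate_tumor(as_parameter_set(fast),
                       dose_schedule(label = "untreated"),
                       T0 = 900, t_end = 30, dt = 0.1, cap = 1e5)
  expect_true(tr$overflow)
  expect_lt(tr$overflow_time, 30)
  expect_equal(max(tr$states[, "T"]), 1e5, tolerance = 1e-6)
  expect_lte(max(tr$times), tr$overflow_time + 1e-9)
})

test_that("simulation input contracts are enforced", {
  expect_error(simulate_tumor(FIXTURE, T0 = -5, t_end = 10), "T0")
  expect_error(simulate_tumor(FIXTURE, T0 = 500, t_end = -1), "t_end")
  expect_error(simulate_tumor(FIXTURE, T0 = 1e9, t_end = 1, cap = 1e8),
               "overflow cap")
  expect_error(trajectory_at(
    simulate_tumor(FIXTURE, T0 = 500, t_end = 5), at = 7), "outside")
})
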