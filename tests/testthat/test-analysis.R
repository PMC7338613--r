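test_that("immune peak extraction refines an injected analytic curve", {
  tt <- seq(0, 30, 0.1)
  tr <- fake_trajectory(tt, I = tt * exp(-tt / 5))
  pk <- peak_immune_time(tr)
  expect_equal(pk$peak_day, 5, tolerance = 1e-3)  # argmax of t e^(-t/5)
  expect_false(pk$at_boundary)

  # monotone decreasing immune curve: peak at window start, flagged
  tr2 <- fake_trajectory(tt, I = exp(-tt / 4))
  pk2 <- peak_immune_time(tr2, window = c(2, 20))
  expect_equal(pk2$peak_day, 2)
  expect_true(pk2$at_boundary)

  expect_error(peak_immune_time(tr, window = c(10, 40)), "window")
})

test_that("normalization sets baselines to 100 and averages across subjects", {
  days <- c(0, 3, 6)
  one <- data.frame(subject_id = "a", arm = "x", day = days,
                    volume_mm3 = c(250, 500, 125))
  s1 <- normalize_and_average(one)
  expect_equal(s1$mean_normalized, c(100, 200, 50))

  # scale invariance: v and 2v normalize identically
  two <- rbind(one, data.frame(subject_id = "b", arm = "x", day = days,
                               volume_mm3 = 2 * c(250, 500, 125)))
  s2 <- normalize_and_average(two)
  expect_equal(s2$mean_normalized, s1$mean_normalized)
  expect_equal(s2$n_subjects, rep(2L, 3))

  # hand-computed three-subject mean, with partial coverage reported
  three <- rbind(
    data.frame(subject_id = "a", arm = "x", day = days,
               volume_mm3 = c(200, 400, 600)),
    data.frame(subject_id = "b", arm = "x", day = days,
               volume_mm3 = c(100, 300, 100)),
    data.frame(subject_id = "c", arm = "x", day = c(0, 3),
               volume_mm3 = c(400, 400)))
  s3 <- normalize_and_average(three)
  expect_equal(s3$mean_normalized,
               c(100, mean(c(200, 300, 100)), mean(c(300, 100))))
  expect_equal(s3$n_subjects, c(3L, 3L, 2L))

  bad <- data.frame(subject_id = "z", arm = "x", day = days,
                    volume_mm3 = c(0, 10, 20))
  expect_error(normalize_and_average(bad), "z")
})

test_that("escape classification follows the rebound and suppression rules", {
  days <- 0:4
  esc <- classify_escape(c(1000, 100, 250, 400, 800), days)
  expect_equal(esc$status, "escaped")
  expect_equal(esc$rebound_day, 2)  # first crossing of 2 x minimum
  expect_equal(esc$min_day, 1)

  sup <- classify_escape(c(1000, 600, 300, 200, 100), days)
  expect_equal(sup$status, "suppressed")
  expect_true(is.na(sup$rebound_day))

  reg <- classify_escape(c(1000, 700, 650, 640, 700), days)
  expect_equal(reg$status, "regressing")

  # untreated exponential growth has no interior minimum
  prog <- classify_escape(1000 * exp(0.18 * days), days)
  expect_equal(prog$status, "progressing")

  # invariance to uniform volume rescaling
  esc2 <- classify_escape(50 * c(1000, 100, 250, 400, 800), days)
  expect_equal(esc2[c("status", "rebound_day")],
               esc[c("status", "rebound_day")])

  expect_error(classify_escape(c(10, 5), c(0, 1)), "3 time points")
})

test_that("kill attribution closes the tumor mass balance", {
  # no drug, no immune response: both kill integrals vanish
  tr0 <- simulate_tumor(FIXTURE, dose_schedule(label = "untreated"),
                        T0 = 400, t_end = 10, dt = 0.05)
  k0 <- attribute_kill(tr0)
  expect_equal(k0$drug_kill, 0)
  expect_equal(k0$immune_kill, 0)

  # kd = 0 switches off immune kill only
  nokd <- unclass(FIXTURE)
  nokd["kd"] <- 1e-12
  tr1 <- simulate_tumor(as_parameter_set(nokd),
                        build_schedule("1-CPA", 10), T0 = 800,
                        t_end = 10, dt = 0.02)
  k1 <- attribute_kill(tr1)
  expect_lt(k1$immune_kill, 1e-6)
  expect_gt(k1$drug_kill, 0)

  # mass balance on a dosed trajectory, quadrature tolerance
  tr2 <- simulate_tumor(FIXTURE, build_schedule("3-CPA", 20), T0 = 900,
                        t_end = 20, dt = 0.02)
  k2 <- attribute_kill(tr2)
  dT <- tr2$states[nrow(tr2$states), "T"] - tr2$states[1, "T"]
  balance <- k2$growth - k2$drug_kill - k2$immune_kill
  turnover <- k2$growth + k2$drug_kill + k2$immune_kill
  expect_lt(abs(dT - balance) / max(abs(dT), turnover), 1e-4)

  expect_error(attribute_kill(tr0, horizon = c(5, 20)), "horizon")
})

test_that("regimen predictions order escapes by inter-dose interval", {
  pred <- predict_regimens(FIXTURE,
                           c("CPA/6-days", "CPA/9-days", "CPA/12-days"),
                           T0_grid = c(300, 650, 1000), t_end = 45,
                           dt = 0.1)
  counts <- escape_counts(pred)
  n <- stats::setNames(counts$n_escaped, counts$regimen)
  expect_lte(n[["CPA/6-days"]], n[["CPA/9-days"]])
  expect_lte(n[["CPA/9-days"]], n[["CPA/12-days"]])

  # every-6-day dosing beats every-12-day dosing for the largest tumors
  df <- as.data.frame(pred)
  f6 <- df$final_volume[df$regimen == "CPA/6-days" & df$T0 == 1000]
  f12 <- df$final_volume[df$regimen == "CPA/12-days" & df$T0 == 1000]
  expect_lt(f6, f12)

  # untreated growth is monotone for every initial volume
  pu <- predict_regimens(FIXTURE, "untreated", T0_grid = c(300, 1000),
                         t_end = 20, dt = 0.1)
  for (tr in attr(pu, "trajectories")) {
    expect_false(is.unsorted(tr$states[, "T"]))
  }
  expect_true(all(as.data.frame(pu)$status == "progressing"))

  # normalized summaries start at 100 by construction
  for (s in attr(pred, "summaries")) {
    expect_equal(s$mean_normalized[1], 100)
  }
  expect_error(predict_regimens(FIXTURE, "CPA/5-days"), "unknown")
})
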