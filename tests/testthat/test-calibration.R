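test_that("objective is zero at truth on noise-free data", {
  coh <- tiny_cohort(seed = 4, noise = 0)
  obj <- fit_objective(attr(coh, "truth"), coh)
  expect_lt(as.numeric(obj), 1e-6)
  expect_equal(attr(obj, "n_penalized"), 0L)
})

test_that("a single e-fold residual gives unit log loss", {
  # one subject, one post-baseline point, observed = e * simulated
  d <- 6
  sim <- 500 * exp(FIXTURE[["ka"]] * d)
  data <- data.frame(subject_id = "s1", arm = "untreated",
                     day = c(0, d), volume_mm3 = c(500, exp(1) * sim))
  expect_equal(as.numeric(fit_objective(FIXTURE, data)), 1,
               tolerance = 1e-5)
})

test_that("objective degrades monotonically away from truth", {
  coh <- generate_cohort(cohort_spec(arms = c("untreated" = 4),
                                     noise_sd_log = 0, seed = 6,
                                     measurement_days = seq(0, 24, 6)))
  truth <- attr(coh, "truth")
  worse <- unclass(truth)
  worse["ka"] <- worse["ka"] * 2
  expect_lt(as.numeric(fit_objective(truth, coh)),
            as.numeric(fit_objective(as_parameter_set(worse), coh)))
})

test_that("objective is invariant to row and subject ordering", {
  coh <- tiny_cohort(seed = 13, noise = 0.1)
  o1 <- as.numeric(fit_objective(FIXTURE, coh))
  shuffled <- coh[sample(nrow(coh)), ]
  expect_equal(as.numeric(fit_objective(FIXTURE, shuffled)), o1,
               tolerance = 1e-12)
})

test_that("objective enforces bounds and non-empty data", {
  coh <- tiny_cohort(seed = 4, noise = 0)
  b <- default_fit_bounds()
  outside <- unclass(FIXTURE)
  outside["kb"] <- 1e5
  expect_error(fit_objective(as_parameter_set(outside), coh, bounds = b),
               "outside bounds.*kb")
  expect_error(fit_objective(FIXTURE, coh[0, ]), "empty")
})

test_that("multistart from the truth start stays at the optimum", {
  coh <- tiny_cohort(seed = 4, noise = 0)
  cfg <- fit_config(n_starts = 1, seed = 1, maxiter = 25)
  fits <- multistart_fit(coh, cfg, starts = attr(coh, "truth"))
  bf <- best_fit(fits)
  expect_lt(bf$objective, 1e-6)
  expect_equal(unclass(bf$params), unclass(attr(coh, "truth")),
               tolerance = 1e-3)
  expect_true(bf$near_optimal)
})

test_that("multistart is reproducible given the seed", {
  coh <- tiny_cohort(seed = 21, noise = 0.15)
  cfg <- fit_config(n_starts = 6, refine_top = 2, seed = 33, maxiter = 4)
  f1 <- multistart_fit(coh, cfg)
  f2 <- multistart_fit(coh, cfg)
  expect_equal(fits_table(f1), fits_table(f2), tolerance = 1e-15)
  expect_equal(f1$screening, f2$screening)
  # results are sorted ascending by objective
  objs <- vapply(f1$results, `[[`, numeric(1), "objective")
  expect_false(is.unsorted(objs))
})

test_that("outlier flagging isolates a scaled subject and respects MAD degeneracy", {
  coh <- generate_cohort(cohort_spec(arms = c("untreated" = 9),
                                     noise_sd_log = 0.05, seed = 17,
                                     measurement_days = seq(0, 24, 6)))
  bad <- unique(coh$subject_id)[5]
  coh$volume_mm3[coh$subject_id == bad & coh$day > 0] <-
    coh$volume_mm3[coh$subject_id == bad & coh$day > 0] * 20
  fit <- structure(list(params = attr(coh, "truth")), class = "mi_fit")

  flagged <- flag_outliers(coh, fit, policy = "robust_flag")
  tab <- attr(flagged, "subject_residuals")
  expect_identical(tab$subject_id[tab$outlier], bad)
  expect_true(all(flagged$outlier[flagged$subject_id == bad]))
  expect_false(any(flagged$outlier[flagged$subject_id != bad]))

  # policy "none" annotates without flagging
  none <- flag_outliers(coh, policy = "none")
  expect_false(any(none$outlier))

  # identical subjects: zero MAD must flag nothing
  days <- seq(0, 18, 6)
  same <- do.call(rbind, lapply(1:6, function(i)
    data.frame(subject_id = paste0("s", i), arm = "untreated",
               day = days, volume_mm3 = 400 * exp(0.18 * days))))
  fit2 <- structure(list(params = FIXTURE), class = "mi_fit")
  expect_false(any(flag_outliers(same, fit2,
                                 policy = "robust_flag")$outlier))

  expect_error(flag_outliers(coh, fit, policy = "median_cut"),
               "should be one of")
  expect_error(flag_outliers(coh, policy = "robust_flag"), "needs a fit")
})
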