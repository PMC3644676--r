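# Synthetic cohort: lag dynamics, response simulation, BOLD geometry and
# behavior-coupled activation.

test_that("subject profiles respect their invariants and are seeded", {
  p1 <- subject_profiles(10, seed = 4)
  p2 <- subject_profiles(10, seed = 4)
  expect_identical(p1, p2)
  expect_true(all(p1$baseline_lag_ms <= 0))
  expect_true(all(p1$rate_repeated >= 0))
  expect_true(all(p1$rate_random >= 0))
})

test_that("programmed lags decay exponentially and favor the repeated kind", {
  prof <- data.frame(baseline_lag_ms = -300, rate_repeated = 0.4,
                     rate_random = 0.1)
  expect_equal(lag_on_day(prof, 1, "repeated"), -300)
  expect_equal(lag_on_day(prof, 7, "repeated"), -300 * exp(-0.4 * 6))
  expect_equal(lag_on_day(prof, 7, "random"), -300 * exp(-0.1 * 6))
  # positive lag difference score (weight) by retention
  expect_gt(lag_on_day(prof, 7, "repeated") - lag_on_day(prof, 7, "random"), 0)
})

test_that("simulated responses round-trip through the lag estimator", {
  rep_seg <- test_repeated()
  quiet <- data.frame(subject_id = 1, baseline_lag_ms = 0, rate_repeated = 0.4,
                      rate_random = 0.1, motor_noise_sd = 0)
  expect_identical(simulate_response(rep_seg, quiet, 1, "repeated", seed = 1),
                   rep_seg$samples)

  lagged <- quiet
  lagged$baseline_lag_ms <- -100
  resp <- simulate_response(rep_seg, lagged, 1, "repeated", seed = 1)
  r <- estimate_lag(tracking_record(rep_seg$samples, resp))
  expect_identical(r$lag_ms, -100)
  expect_equal(r$r2, 1, tolerance = 1e-6)

  # measured weights recover the programmed day-7 sign
  profs <- subject_profiles(4, seed = 8)
  sc <- simulate_scan_day_scores(profs, 7, rep_seg, test_random_pool(5),
                                 seed = 99, segments_per_condition = 5)
  ds <- difference_scores(sc, day = 7, measures = "lag")
  truth_sign <- sign(vapply(seq_len(4), function(s)
    lag_on_day(profs[s, ], 7, "repeated") - lag_on_day(profs[s, ], 7, "random"),
    numeric(1)))
  expect_identical(sign(ds$weight[match(profs$subject_id, ds$subject_id)]),
                   truth_sign)
})

test_that("the block schedule and run geometry match the design", {
  sch <- run_block_schedule(1)
  expect_identical(sch$onset_s, c(40, 230))
  expect_identical(sch$duration_s, c(150, 150))
  expect_setequal(sch$condition, c("repeated", "random"))
  # order counterbalanced across runs
  expect_identical(run_block_schedule(2)$condition, rev(sch$condition))

  # 420 s at TR 2 -> 210 volumes per run
  truth <- bold_truth(c(6, 6, 6))
  prof <- subject_profiles(1, seed = 1)[1, ]
  sess <- simulate_bold_session(prof, 50, truth, seed = 1, n_runs = 2)
  expect_identical(vapply(sess$runs, nrow, 1L), c(210L, 210L))
  expect_identical(ncol(sess$runs[[1]]), 216L)
  expect_identical(vapply(sess$motion, dim, c(1L, 1L))[1, ], c(210L, 210L))
})

test_that("truth layouts reject overlapping regions", {
  expect_error(bold_truth(c(10, 10, 10), regions = list(
    list(name = "a", rule = "null", corner = c(1, 1, 1), size = 4),
    list(name = "b", rule = "null", corner = c(3, 3, 3), size = 4))),
    "disjoint")
  expect_error(bold_truth(c(6, 6, 6), regions = list(
    list(name = "a", rule = "null", corner = c(4, 4, 4), size = 4))),
    "exceeds")
})

test_that("noiseless coupled activation is linear in the behavioral weight", {
  truth <- bold_truth(c(10, 10, 10))
  prof <- subject_profiles(1, seed = 2)[1, ]
  prof$coupling_gain <- 0.05
  quiet <- list(noise_sd = 0, drift_sd = 0, motion_amplitude = 1e-3,
                motion_leak = 0)

  fit_contrast <- function(w) {
    sess <- do.call(simulate_bold_session,
                    c(list(prof, w, truth, seed = 3, n_runs = 2), quiet))
    fit <- fit_glm(sess$runs, build_design(sess$schedules, 210, sess$motion))
    list(con = contrast_repeated_minus_random(fit, type = "beta",
                                              grid_dims = c(10, 10, 10)),
         true = sess$true_contrast)
  }

  a <- fit_contrast(100)
  expect_equal(as.numeric(a$con$values), a$true, tolerance = 1e-7)
  expect_equal(max(abs(a$con$values[truth$masks$null])), 0, tolerance = 1e-7)
  expect_equal(mean(a$con$values[truth$masks$coupled]), 0.05 * 100,
               tolerance = 1e-7)

  b <- fit_contrast(200)
  expect_equal(mean(b$con$values[truth$masks$coupled]),
               2 * mean(a$con$values[truth$masks$coupled]), tolerance = 1e-6)

  # zero coupling and zero weight: contrast vanishes everywhere
  z <- fit_contrast(0)
  expect_lt(max(abs(z$con$values[!truth$masks$uniform])), 1e-7)
})

test_that("identical seeds give bit-identical sessions", {
  truth <- bold_truth(c(8, 8, 8))
  prof <- subject_profiles(1, seed = 5)[1, ]
  s1 <- simulate_bold_session(prof, 80, truth, seed = 11, n_runs = 1)
  s2 <- simulate_bold_session(prof, 80, truth, seed = 11, n_runs = 1)
  expect_identical(s1$runs, s2$runs)
  expect_identical(s1$motion, s2$motion)
})
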