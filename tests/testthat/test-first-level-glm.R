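# Design construction, OLS fitting, the Repeated-Random contrast and
# Gaussian smoothing.

test_that("the design matrix has the documented structure", {
  sch <- lapply(1:4, run_block_schedule)
  mo <- lapply(1:4, function(i) matrix(rnorm(210 * 6, 0, 0.1), 210, 6))
  X <- build_design(sch, 210, mo)
  expect_identical(dim(X), c(840L, 16L))  # 2 task + 6 motion + 2 per run

  X1 <- build_design(sch[1], 210, mo[1])
  expect_identical(nrow(X1), 210L)  # one 420-s run at TR 2

  # task regressors are zero during the initial rest
  rest_rows <- 1:10  # first 20 s
  expect_true(all(X1[rest_rows, c("task_repeated", "task_random")] == 0))
  expect_gt(max(X1[, "task_repeated"]), 0.9)

  # a rest-only schedule leaves the task columns empty
  rest_only <- list(data.frame(onset_s = numeric(), duration_s = numeric(),
                               condition = character()))
  X0 <- build_design(rest_only, 210, mo[1])
  expect_true(all(X0[, c("task_repeated", "task_random")] == 0))

  expect_error(build_design(sch, 210, mo[1:2]), "one matrix per run")
  expect_error(build_design(sch[1], 210, list(matrix(0, 100, 6))), "210 x 6")
})

test_that("OLS recovers programmed amplitudes exactly without noise", {
  sch <- lapply(1:2, run_block_schedule)
  mo <- lapply(1:2, function(i) matrix(rnorm(210 * 6, 0, 0.1), 210, 6))
  X <- build_design(sch, 210, mo)
  beta_true <- c(task_repeated = 7, task_random = 3)
  y <- X[, "task_repeated"] * beta_true[1] + X[, "task_random"] * beta_true[2] +
    100 + X[, "motion1"] * 2
  fit <- fit_glm(cbind(y, y * 2), X)
  expect_equal(unname(fit$beta["task_repeated", 1]), 7, tolerance = 1e-8)
  expect_equal(unname(fit$beta["task_random", 1]), 3, tolerance = 1e-8)
  expect_equal(unname(fit$beta["task_repeated", 2]), 14, tolerance = 1e-8)
  expect_identical(fit$df, 420L - 12L)

  con <- contrast_repeated_minus_random(fit, type = "beta")
  expect_equal(unname(con$values), c(4, 8), tolerance = 1e-8)

  # constant time series: task betas zero
  fitc <- fit_glm(matrix(5, 420, 1), X)
  expect_lt(max(abs(fitc$beta[c("task_repeated", "task_random"), 1])), 1e-10)

  # duplicated column is reported by name
  Xbad <- cbind(X, task_repeated2 = X[, "task_repeated"])
  expect_error(fit_glm(matrix(rnorm(420), 420, 1), Xbad), "task_repeated2")
})

test_that("contrast t statistics are Student-t distributed under the null", {
  set.seed(13)
  sch <- lapply(1:2, run_block_schedule)
  mo <- lapply(1:2, function(i) matrix(rnorm(210 * 6, 0, 0.1), 210, 6))
  X <- build_design(sch, 210, mo)
  Y <- matrix(rnorm(420 * 5000), 420, 5000)
  fit <- fit_glm(Y, X)
  con <- contrast_repeated_minus_random(fit, type = "t")
  expect_lt(abs(mean(con$values)), 0.1)
  ks <- ks.test(con$values, function(q) pt(q, df = fit$df))
  expect_gt(ks$p.value, 0.01)

  # zero-variance voxels are capped and flagged
  fit0 <- fit_glm(cbind(X[, "task_repeated"] * 2, Y[, 1]), X)
  con0 <- contrast_repeated_minus_random(fit0, type = "t")
  expect_true(con0$capped[1])
  expect_false(con0$capped[2])
  expect_true(is.finite(con0$values[1]))
})

test_that("motion regressors absorb motion-correlated artifacts", {
  set.seed(19)
  sch <- list(run_block_schedule(1))
  x_task <- hrf_regressor(c(40, 230), 150, 210, 2)
  # motion trace correlated with the task
  m1 <- 0.8 * x_task + as.numeric(stats::filter(rnorm(210, 0, 0.3),
                                                rep(0.2, 5), sides = 1))
  m1[is.na(m1)] <- 0
  mo <- list(cbind(m1, matrix(rnorm(210 * 5, 0, 0.1), 210, 5)))
  X <- build_design(sch, 210, mo)
  true_contrast <- 5
  y <- X[, "task_repeated"] * (10 + true_contrast) +
    X[, "task_random"] * 10 + 40 * X[, "motion1"] + rnorm(210, 0, 0.5)

  fit_full <- fit_glm(matrix(y), X)
  con_full <- contrast_repeated_minus_random(fit_full, "beta")$values
  expect_lt(abs(con_full - true_contrast) / true_contrast, 0.05)

  X_nomo <- X[, !grepl("^motion", colnames(X))]
  fit_nomo <- fit_glm(matrix(y), X_nomo)
  con_nomo <- contrast_repeated_minus_random(fit_nomo, "beta")$values
  expect_gt(abs(con_nomo - true_contrast) / true_contrast, 0.20)
})

test_that("Gaussian smoothing has the requested FWHM and fixed points", {
  vol <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(smooth_volumes(vol, 0), vol)
  expect_error(smooth_volumes(vol, -1), "non-negative")

  # constants are preserved exactly, including at edges
  expect_equal(smooth_volumes(array(5, c(8, 8, 8)), 4), array(5, c(8, 8, 8)),
               tolerance = 1e-12)

  # impulse response width: fit the half-maximum crossing by interpolation
  g <- array(0, c(31, 31, 31))
  g[16, 16, 16] <- 1
  sm <- smooth_volumes(g, 4, voxel_mm = 1)
  for (axis_profile in list(sm[, 16, 16], sm[16, , 16], sm[16, 16, ])) {
    half <- max(axis_profile) / 2
    above <- which(axis_profile >= half)
    lo <- min(above); hi <- max(above)
    cross <- function(ia, ib) ia + (half - axis_profile[ia]) /
      (axis_profile[ib] - axis_profile[ia]) * (ib - ia)
    fwhm <- cross(hi, hi + 1) - cross(lo, lo - 1)
    expect_lt(abs(fwhm - 4) / 4, 0.05)
  }

  # 4D smoothing treats volumes independently
  ser <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  sm4 <- smooth_volumes(ser, 4)
  expect_equal(sm4[, , , 2], smooth_volumes(ser[, , , 2], 4),
               tolerance = 1e-12)
})
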