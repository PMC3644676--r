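# Stimulus synthesis: rendering, centering/zeroing, difficulty screens,
# seeded sampling and the counterbalanced schedule.

test_that("render_segment evaluates the sinusoidal series over one period", {
  n <- 500
  x <- 2 * pi * (seq_len(n) - 1) / (n - 1)

  zero <- render_segment(segment_coefficients())
  expect_equal(zero$samples, rep(0, n))

  s1 <- render_segment(segment_coefficients(a = c(1, 0, 0, 0, 0, 0)))
  expect_equal(s1$samples, sin(x), tolerance = 1e-12)
  expect_equal(segment_rom(s1), 2, tolerance = 1e-4)
  expect_equal(s1$samples[c(1, n)], c(0, 0), tolerance = 1e-12)

  c1 <- render_segment(segment_coefficients(b0 = -1, b = c(1, 0, 0, 0, 0, 0)))
  expect_equal(c1$samples, cos(x) - 1, tolerance = 1e-12)
  expect_equal(c1$samples[c(1, n)], c(0, 0), tolerance = 1e-12)
  expect_equal(min(c1$samples), -2, tolerance = 1e-4)

  expect_equal(length(render_segment(segment_coefficients(),
                                     duration_s = 10,
                                     sample_rate = 50)$samples), 500)
  expect_error(render_segment(c(rep(0, 12), NaN)), "finite")
})

test_that("rendering is periodic: f(0) equals f(2*pi) for any coefficients", {
  set.seed(11)
  for (i in 1:25) {
    seg <- render_segment(segment_coefficients(
      b0 = runif(1, -5, 5), a = runif(6, -10, 10), b = runif(6, -10, 10)))
    n <- length(seg$samples)
    expect_equal(seg$samples[1], seg$samples[n], tolerance = 1e-9)
  }
})

test_that("center_and_zero applies the midline offset and zeroes endpoints", {
  n <- 500
  x <- 2 * pi * (seq_len(n) - 1) / (n - 1)

  # cos(x) - 1 has midline (max + min) / 2 = -1
  c1 <- center_and_zero(render_segment(
    segment_coefficients(b0 = -1, b = c(1, 0, 0, 0, 0, 0))))
  expect_equal(c1$midline_offset, -1, tolerance = 1e-4)
  expect_identical(c1$samples[c(1, n)], c(0, 0))
  expect_equal(segment_rom(c1), 2, tolerance = 1e-4)

  # already symmetric sin(x) is a fixed point
  s1 <- center_and_zero(render_segment(
    segment_coefficients(a = c(1, 0, 0, 0, 0, 0))))
  expect_equal(s1$samples, sin(x), tolerance = 1e-12)
  expect_identical(s1$samples[c(1, n)], c(0, 0))

  # arbitrary endpoints are pulled to zero by the ramp
  raw <- make_segment(seq(0.4, -0.2, length.out = 100) + sin(seq(0, 7, length.out = 100)))
  adj <- center_and_zero(raw)
  expect_identical(adj$samples[c(1, 100)], c(0, 0))

  expect_error(center_and_zero(make_segment(rep(3, 100))), "constant")
})

test_that("difficulty screens compare ROM, velocity and junction slopes", {
  rep_seg <- test_repeated()

  self <- screen_random(rep_seg, rep_seg)
  expect_true(self$rom_ok)
  expect_true(self$velocity_ok)
  expect_true(self$slope_ok)
  expect_true(self$pass)

  # 10% larger ROM violates the 5% tolerance (slopes scale by only 10%)
  big <- make_segment(rep_seg$samples * 1.10)
  rb <- screen_random(big, rep_seg)
  expect_false(rb$rom_ok)
  expect_true(rb$slope_ok)

  # half-amplitude copy halves the mean |velocity|
  half <- make_segment(rep_seg$samples * 0.5)
  rh <- screen_random(half, rep_seg, velocity_floor_frac = 0.8)
  expect_false(rh$velocity_ok)

  expect_error(screen_random(make_segment(rnorm(100)), rep_seg), "share"
  )
})

test_that("seeded sampling is deterministic and screens stay satisfied", {
  rep_seg <- test_repeated()
  s1 <- sample_random_segment(5, rep_seg)
  s2 <- sample_random_segment(5, rep_seg)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$attempts, s2$attempts)

  pool <- test_random_pool(10)
  for (seg in pool) {
    rp <- screen_random(seg, rep_seg)
    expect_true(rp$pass)
    expect_lte(max(abs(seg$samples)), 20)
    # screens are stable under re-application of center_and_zero
    rp2 <- screen_random(center_and_zero(seg), rep_seg)
    expect_true(rp2$pass)
  }
})

test_that("disabling the screens accepts the first in-range candidate", {
  rep_seg <- test_repeated()
  seg <- sample_random_segment(42, rep_seg, rom_tolerance = 100,
                               velocity_floor_frac = 0, slope_tolerance = 1e6,
                               limit_deg = Inf)
  expect_identical(seg$attempts, 1L)
})

test_that("generation failure reports which screens rejected candidates", {
  rep_seg <- test_repeated()
  expect_error(sample_random_segment(1, rep_seg, max_attempts = 500),
               "rejects")
})

test_that("schedules are counterbalanced within blocks", {
  one <- build_schedule(10, block_size = 10, seed = 3)
  expect_identical(nrow(one), 10L)
  expect_identical(sum(one$order_flag == "repeated_first"), 5L)

  full <- build_schedule(50, n_days = 5, seed = 3)
  expect_identical(nrow(full), 250L)
  counts <- table(full$day, full$block, full$order_flag)
  expect_true(all(counts == 5L))

  expect_identical(nrow(build_schedule(0)), 0L)
  expect_error(build_schedule(10, block_size = 5), "even")
  expect_error(build_schedule(12, block_size = 10), "multiple")
})
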