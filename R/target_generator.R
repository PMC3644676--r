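# Target stimulus synthesis for the continuous tracking task.
#
# Each 10-s segment is one period of a sinusoidal series
#   f(x) = b0 + a1 sin(x) + b1 cos(x) + ... + a6 sin(6x) + b6 cos(6x)
# rendered at the joystick sampling rate. A fixed coefficient set defines the
# covertly repeated segment; random segments draw coefficients uniformly from
# [-10, 10] and must pass difficulty-equating screens against the repeated
# segment before being accepted.

# cache of Fourier bases keyed by sample count
.basis_cache <- new.env(parent = emptyenv())

fourier_basis <- function(n, n_harmonics = 6L) {
  key <- sprintf("%d_%d", n, n_harmonics)
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  x <- 2 * pi * (seq_len(n) - 1) / (n - 1)
  B <- cbind(1, sapply(seq_len(n_harmonics), function(k) sin(k * x)),
             sapply(seq_len(n_harmonics), function(k) cos(k * x)))
  colnames(B) <- c("b0", paste0("a", seq_len(n_harmonics)),
                   paste0("b", seq_len(n_harmonics)))
  .basis_cache[[key]] <- B
  B
}

#' Build a sinusoidal-series coefficient vector
#'
#' Assembles the 13 coefficients of the segment series (offset `b0`, sine
#' amplitudes `a1..a6`, cosine amplitudes `b1..b6`) into the named vector the
#' rendering functions expect.
#'
#' @param b0 Offset (degrees).
#' @param a Numeric vector of 6 sine amplitudes (degrees).
#' @param b Numeric vector of 6 cosine amplitudes (degrees).
#' @return Named numeric vector of length 13.
#' @export
#' @examples
#' segment_coefficients(a = c(1, 0, 0, 0, 0, 0))
segment_coefficients <- function(b0 = 0, a = numeric(6), b = numeric(6)) {
  if (length(a) != 6L || length(b) != 6L)
    stop("`a` and `b` must each have length 6", call. = FALSE)
  coeffs <- c(b0 = b0, setNames(a, paste0("a", 1:6)),
              setNames(b, paste0("b", 1:6)))
  check_finite(coeffs, "coefficients")
  coeffs
}

#' Default repeated-segment coefficients
#'
#' A fixed coefficient set used for the covertly repeated segment. This is a
#' synthetic stand-in drawn once from the same uniform [-10, 10] coefficient
#' family as the random pool and frozen; it was selected to be typical of
#' candidates that survive the display limit: excursion inside +/-20 degrees
#' after centering, range of motion near the screened pool's mode (~35
#' degrees), clearly non-zero junction slope (~25 deg/s) and mid-pool average
#' velocity (~17 deg/s). It is not tied to any particular experiment's
#' stimulus.
#'
#' @return Named numeric coefficient vector (see [segment_coefficients()]).
#' @export
default_repeated_coefficients <- function() {
  segment_coefficients(
    b0 = 0,
    a = c(7.7377, -5.3172, -6.7503, -2.4269, -2.8908, -0.6954),
    b = c(-7.5351, 0.8236, 2.4993, 2.9322, 2.6208, -2.3148))
}

#' Render a target segment from sinusoidal-series coefficients
#'
#' Evaluates the series over one full period, `x_i = 2*pi*i/(N-1)` for
#' `i = 0..N-1`, so the first and last samples coincide by periodicity.
#'
#' @param coeffs Coefficient vector from [segment_coefficients()].
#' @param duration_s Segment duration in seconds (default 10).
#' @param sample_rate Sampling rate in Hz (default 50).
#' @param kind `"repeated"` or `"random"`.
#' @return A `ct_segment` object: list with `kind`, `coefficients`,
#'   `samples` (degrees), `duration_s`, `sample_rate`.
#' @export
#' @examples
#' seg <- render_segment(segment_coefficients(a = c(1, 0, 0, 0, 0, 0)))
#' range(seg$samples)
render_segment <- function(coeffs, duration_s = 10, sample_rate = 50,
                           kind = c("random", "repeated")) {
  kind <- match.arg(kind)
  check_scalar(duration_s, "duration_s", 0, strict = TRUE)
  check_scalar(sample_rate, "sample_rate", 0, strict = TRUE)
  if (length(coeffs) != 13L) stop("expected 13 coefficients", call. = FALSE)
  check_finite(coeffs, "coeffs")
  n <- round(duration_s * sample_rate)
  samples <- drop(fourier_basis(n) %*% as.numeric(coeffs))
  structure(list(kind = kind, coefficients = coeffs, samples = samples,
                 duration_s = duration_s, sample_rate = sample_rate),
            class = "ct_segment")
}

#' @export
print.ct_segment <- function(x, ...) {
  cat(sprintf("<ct_segment> %s, %g s @ %g Hz, ROM %.2f deg\n",
              x$kind, x$duration_s, x$sample_rate, segment_rom(x)))
  invisible(x)
}

#' Peak-to-peak range of motion of a segment (degrees)
#' @param seg A `ct_segment`.
#' @return Range of motion in degrees.
#' @export
segment_rom <- function(seg) max(seg$samples) - min(seg$samples)

#' Mean absolute velocity of a segment (degrees per second)
#' @param seg A `ct_segment`.
#' @return Mean absolute sample-to-sample velocity, deg/s.
#' @export
segment_mean_abs_velocity <- function(seg)
  mean(abs(diff(seg$samples))) * seg$sample_rate

#' Center a segment on the midline and zero its endpoints
#'
#' Two-step adjustment mirroring how segments are prepared for display:
#' first the samples are shifted so the minimum and maximum are equidistant
#' from the screen midline (offset by `(max + min) / 2`); then a linear ramp
#' between the two endpoint values is subtracted so both endpoints land
#' exactly on 0, which is where consecutive segments are linked. For a
#' periodically rendered segment the ramp is (numerically) a constant, so the
#' interior shape and velocity profile are untouched and the range of motion
#' is preserved.
#'
#' @param seg A rendered `ct_segment`.
#' @return The adjusted segment, with the applied midline offset stored in
#'   `$midline_offset`.
#' @export
center_and_zero <- function(seg) {
  s <- seg$samples
  if ((max(s) - min(s)) < 1e-9)
    stop("constant segment (zero range of motion) cannot be centered",
         call. = FALSE)
  offset <- (max(s) + min(s)) / 2
  s <- s - offset
  n <- length(s)
  ramp <- s[1] + (s[n] - s[1]) * (seq_len(n) - 1) / (n - 1)
  s <- s - ramp
  seg$samples <- s
  seg$midline_offset <- offset
  seg
}

slope_at_start <- function(seg) (seg$samples[2] - seg$samples[1]) * seg$sample_rate
slope_at_end <- function(seg) {
  n <- length(seg$samples)
  (seg$samples[n] - seg$samples[n - 1]) * seg$sample_rate
}

#' Screen a random segment against the repeated segment
#'
#' Applies the three difficulty-equating screens: the random segment's range
#' of motion must be within `rom_tolerance` (5%) of the repeated segment's;
#' its mean absolute velocity must be at least `velocity_floor_frac` of the
#' repeated segment's; and its junction slopes must be within
#' `slope_tolerance` (20%) of the repeated segment's slope at both possible
#' link orderings (random-then-repeated and repeated-then-random), so an
#' accepted segment can occupy either trial position.
#'
#' @param seg Candidate random `ct_segment`.
#' @param repeated Repeated `ct_segment` (same duration and rate).
#' @param rom_tolerance Fractional range-of-motion tolerance (default 0.05).
#' @param velocity_floor_frac Velocity floor as a fraction of the repeated
#'   segment's mean absolute velocity (default 0.8).
#' @param slope_tolerance Fractional junction-slope tolerance (default 0.20).
#' @return A `ct_screen_report`: list with `rom`, `mean_abs_velocity`,
#'   `rom_ok`, `velocity_ok`, `slope_ok` and `pass`.
#' @export
screen_random <- function(seg, repeated, rom_tolerance = 0.05,
                          velocity_floor_frac = 0.8, slope_tolerance = 0.20) {
  if (length(seg$samples) != length(repeated$samples) ||
      seg$sample_rate != repeated$sample_rate)
    stop("segments must share duration and sample rate", call. = FALSE)
  rom_r <- segment_rom(seg)
  rom_rep <- segment_rom(repeated)
  vel_r <- segment_mean_abs_velocity(seg)
  vel_rep <- segment_mean_abs_velocity(repeated)
  rom_ok <- abs(rom_r - rom_rep) <= rom_tolerance * rom_rep
  velocity_ok <- vel_r >= velocity_floor_frac * vel_rep
  j1 <- abs(slope_at_end(seg) - slope_at_start(repeated)) <=
    slope_tolerance * abs(slope_at_start(repeated))
  j2 <- abs(slope_at_start(seg) - slope_at_end(repeated)) <=
    slope_tolerance * abs(slope_at_end(repeated))
  structure(list(rom = rom_r, mean_abs_velocity = vel_r,
                 rom_ok = rom_ok, velocity_ok = velocity_ok,
                 slope_ok = j1 && j2,
                 pass = rom_ok && velocity_ok && (j1 && j2)),
            class = "ct_screen_report")
}

#' Draw an accepted random segment
#'
#' Repeatedly draws coefficient vectors (`a1..a6`, `b1..b6` uniform on
#' `coefficient_range`, offset determined by centering), renders and adjusts
#' each candidate, rejects any whose excursion leaves `limit_deg`, and
#' returns the first candidate passing [screen_random()]. Reproducible for a
#' fixed `seed`.
#'
#' @param seed Integer RNG seed.
#' @param repeated Repeated `ct_segment` used as the screening reference.
#' @param max_attempts Attempt cap before giving up (default 10000).
#' @param coefficient_range Length-2 range for random coefficients.
#' @param limit_deg Display excursion limit in degrees (default 20).
#' @inheritParams screen_random
#' @return Accepted random `ct_segment`, with `$attempts` recording how many
#'   draws were needed.
#' @export
sample_random_segment <- function(seed, repeated, max_attempts = 3e6,
                                  coefficient_range = c(-10, 10),
                                  limit_deg = 20, rom_tolerance = 0.05,
                                  velocity_floor_frac = 0.8,
                                  slope_tolerance = 0.20) {
  sample_random_segments(seed, repeated, n = 1, max_attempts = max_attempts,
                         coefficient_range = coefficient_range,
                         limit_deg = limit_deg, rom_tolerance = rom_tolerance,
                         velocity_floor_frac = velocity_floor_frac,
                         slope_tolerance = slope_tolerance)[[1]]
}

#' Draw several accepted random segments from one seeded stream
#'
#' Bulk version of [sample_random_segment()]. Candidates are drawn in fixed
#' batches from a single RNG stream; because the joint acceptance rate of
#' the display limit and the three screens is on the order of 1e-4, the
#' screens are evaluated vectorized, with a cheap exact pre-reject (range of
#' motion measured on a subgrid is a lower bound, so candidates whose
#' subgrid range already exceeds the admissible maximum cannot pass).
#'
#' @inheritParams sample_random_segment
#' @param n Number of accepted segments to return.
#' @return List of `n` accepted random `ct_segment`s, in draw order; each
#'   carries `$attempts`, its 1-based candidate index in the stream.
#' @export
sample_random_segments <- function(seed, repeated, n, max_attempts = 3e6,
                                   coefficient_range = c(-10, 10),
                                   limit_deg = 20, rom_tolerance = 0.05,
                                   velocity_floor_frac = 0.8,
                                   slope_tolerance = 0.20) {
  stopifnot(length(coefficient_range) == 2L, n >= 1)
  nr <- length(repeated$samples)
  rate <- repeated$sample_rate
  B <- fourier_basis(nr)[, -1, drop = FALSE]
  sub <- unique(c(seq(1L, nr, by = 5L), nr))
  Bsub <- B[sub, , drop = FALSE]
  rom_rep <- segment_rom(repeated)
  vel_rep <- segment_mean_abs_velocity(repeated)
  s_start <- slope_at_start(repeated)
  s_end <- slope_at_end(repeated)
  rom_cap <- min(2 * limit_deg, (1 + rom_tolerance) * rom_rep)
  batch <- 5000L
  out <- vector("list", n)
  found <- 0L
  drawn <- 0L
  fails <- c(amplitude = 0L, rom = 0L, velocity = 0L, slope = 0L)
  with_seed(seed, {
    while (found < n && drawn < max_attempts) {
      m <- min(batch, max_attempts - drawn)
      C <- matrix(runif(12L * m, coefficient_range[1], coefficient_range[2]),
                  nrow = 12L)
      Msub <- Bsub %*% C
      subrom <- do.call(pmax, asplit(Msub, 1)) - do.call(pmin, asplit(Msub, 1))
      keep <- which(subrom <= rom_cap)
      # pre-rejects: subgrid ROM already above the cap
      n_pre <- m - length(keep)
      if (length(keep)) {
        M <- B %*% C[, keep, drop = FALSE]
        cmax <- do.call(pmax, asplit(M, 1))
        cmin <- do.call(pmin, asplit(M, 1))
        off <- (cmax + cmin) / 2
        endv <- M[1, ] - off         # endpoint value after centering
        shift <- off + endv          # total shift applied by center_and_zero
        amp_ok <- pmax(abs(cmax - shift), abs(cmin - shift)) <= limit_deg
        rom <- cmax - cmin
        rom_ok <- abs(rom - rom_rep) <= rom_tolerance * rom_rep
        vel <- colMeans(abs(M[-1, , drop = FALSE] - M[-nr, , drop = FALSE])) * rate
        vel_ok <- vel >= velocity_floor_frac * vel_rep
        sl_start <- (M[2, ] - M[1, ]) * rate
        sl_end <- (M[nr, ] - M[nr - 1, ]) * rate
        slope_ok <- abs(sl_end - s_start) <= slope_tolerance * abs(s_start) &
          abs(sl_start - s_end) <= slope_tolerance * abs(s_end)
        pass <- amp_ok & rom_ok & vel_ok & slope_ok
        fails["amplitude"] <- fails["amplitude"] + sum(!amp_ok)
        fails["rom"] <- fails["rom"] + n_pre + sum(amp_ok & !rom_ok)
        fails["velocity"] <- fails["velocity"] + sum(amp_ok & rom_ok & !vel_ok)
        fails["slope"] <- fails["slope"] +
          sum(amp_ok & rom_ok & vel_ok & !slope_ok)
        for (j in which(pass)) {
          if (found >= n) break
          k <- keep[j]
          coeffs <- segment_coefficients(b0 = 0, a = C[1:6, k], b = C[7:12, k])
          seg <- center_and_zero(render_segment(
            coeffs, repeated$duration_s, rate, kind = "random"))
          seg$attempts <- drawn + k
          found <- found + 1L
          out[[found]] <- seg
        }
      } else {
        fails["rom"] <- fails["rom"] + n_pre
      }
      drawn <- drawn + m
    }
  })
  if (found < n)
    stop(sprintf(
      paste0("only %d of %d acceptable random segments in %d attempts ",
             "(rejects: amplitude %d, ROM %d, velocity %d, slope %d)"),
      found, n, drawn, fails["amplitude"], fails["rom"], fails["velocity"],
      fails["slope"]), call. = FALSE)
  out
}

#' Build a counterbalanced trial schedule
#'
#' Each 20-s trial links one repeated and one random 10-s segment; within
#' every block exactly half the trials present the repeated segment first.
#'
#' @param n_trials Trials per day (must be a multiple of `block_size`).
#' @param block_size Trials per block (must be even; default 10).
#' @param n_days Number of days to schedule (default 1).
#' @param seed Integer RNG seed for the within-block order shuffle.
#' @return Data frame with columns `day`, `block`, `trial` (within-day
#'   index) and `order_flag` (`"repeated_first"` / `"random_first"`).
#' @export
#' @examples
#' sched <- build_schedule(50, n_days = 5, seed = 1)
#' nrow(sched)  # 250
build_schedule <- function(n_trials = 50, block_size = 10, n_days = 1,
                           seed = 1) {
  check_scalar(n_trials, "n_trials", 0)
  if (n_trials == 0)
    return(data.frame(day = integer(), block = integer(), trial = integer(),
                      order_flag = character(), stringsAsFactors = FALSE))
  if (block_size %% 2 != 0)
    stop("`block_size` must be even so orders can be counterbalanced",
         call. = FALSE)
  if (n_trials %% block_size != 0)
    stop("`n_trials` must be a multiple of `block_size`", call. = FALSE)
  n_blocks <- n_trials %/% block_size
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_days), function(d) {
      do.call(rbind, lapply(seq_len(n_blocks), function(b) {
        flags <- sample(rep(c("repeated_first", "random_first"),
                            each = block_size / 2))
        data.frame(day = d, block = b,
                   trial = (b - 1) * block_size + seq_len(block_size),
                   order_flag = flags, stringsAsFactors = FALSE)
      }))
    }))
    rownames(out) <- NULL
    out
  })
}
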