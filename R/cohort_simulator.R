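# Synthetic cohort with known ground truth.
#
# Behavior: each subject tracks with a time lag that decays exponentially
# from a (negative) baseline across days, faster for the repeated than for
# the random sequence, plus Gaussian motor noise -- so by retention the
# lag difference score (repeated - random) is positive with known magnitude.
#
# BOLD: block-design runs (40/150/40/150/40 s rest/stimulation at TR 2 s,
# 210 volumes) on a small 3D grid containing seeded regions whose
# Repeated-Random response amplitude follows a per-region rule: coupled to
# the subject's behavioral weight, uniform across subjects, or null.

#' Generate a seeded cohort of subject profiles
#'
#' Baseline lags and day-wise exponential lag-decay rates are drawn per
#' subject; the repeated-sequence rate exceeds the random rate on average,
#' producing a positive lag difference score at retention. Defaults describe
#' a cohort of 10 subjects with ~-300 ms baseline lag, sequence-specific
#' decay 0.4/day versus non-specific 0.1/day, 1 degree of motor noise, and a
#' BOLD coupling gain of 0.05 signal units per ms of behavioral weight.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param seed Integer RNG seed.
#' @param baseline_lag_ms Mean baseline lag in ms (negative; default -300).
#' @param baseline_lag_sd SD of baseline lag across subjects (default 30).
#' @param rate_repeated,rate_repeated_sd Mean and SD of the repeated-sequence
#'   lag decay rate (per day; defaults 0.4, 0.08).
#' @param rate_random,rate_random_sd Mean and SD of the random-sequence decay
#'   rate (defaults 0.1, 0.04).
#' @param motor_noise_sd Motor noise SD in degrees (default 1).
#' @param coupling_gain BOLD amplitude (signal units) per unit behavioral
#'   weight (default 0.05).
#' @return Data frame of subject profiles.
#' @export
subject_profiles <- function(n_subjects = 10, seed = 1,
                             baseline_lag_ms = -300, baseline_lag_sd = 30,
                             rate_repeated = 0.4, rate_repeated_sd = 0.08,
                             rate_random = 0.1, rate_random_sd = 0.04,
                             motor_noise_sd = 1, coupling_gain = 0.05) {
  stopifnot(baseline_lag_ms <= 0, motor_noise_sd >= 0)
  with_seed(seed, data.frame(
    subject_id = seq_len(n_subjects),
    baseline_lag_ms = pmin(baseline_lag_ms +
                             rnorm(n_subjects, 0, baseline_lag_sd), 0),
    rate_repeated = pmax(rnorm(n_subjects, rate_repeated, rate_repeated_sd), 0),
    rate_random = pmax(rnorm(n_subjects, rate_random, rate_random_sd), 0),
    motor_noise_sd = motor_noise_sd,
    coupling_gain = coupling_gain))
}

#' Programmed tracking lag for a subject on a given day
#'
#' Exponential decay toward zero lag:
#' `lag(day) = baseline * exp(-rate * (day - 1))`, with the rate specific to
#' the sequence kind.
#'
#' @param profile One row of [subject_profiles()].
#' @param day Day number (1 = first session).
#' @param kind `"repeated"` or `"random"`.
#' @return Lag in milliseconds (non-positive).
#' @export
lag_on_day <- function(profile, day, kind = c("repeated", "random")) {
  kind <- match.arg(kind)
  rate <- if (kind == "repeated") profile$rate_repeated else profile$rate_random
  profile$baseline_lag_ms * exp(-rate * (day - 1))
}

#' Simulate a subject's joystick response to a target segment
#'
#' The response is the target delayed by the subject's programmed lag for
#' that day and sequence kind (rounded to whole samples; the leading edge is
#' held at the target's first value) plus Gaussian motor noise.
#'
#' @param target A `ct_segment` (or numeric samples vector).
#' @param profile One row of [subject_profiles()].
#' @param day Day number.
#' @param kind Sequence kind, `"repeated"` or `"random"`.
#' @param seed Integer RNG seed for the motor noise.
#' @param sample_rate Sampling rate in Hz; taken from `target` when it is a
#'   `ct_segment`.
#' @return Numeric response samples (degrees).
#' @export
simulate_response <- function(target, profile, day,
                              kind = c("repeated", "random"), seed = 1,
                              sample_rate = 50) {
  kind <- match.arg(kind)
  samples <- if (inherits(target, "ct_segment")) target$samples else target
  if (inherits(target, "ct_segment")) sample_rate <- target$sample_rate
  lag_ms <- lag_on_day(profile, day, kind)
  d <- as.integer(round(-lag_ms / 1000 * sample_rate))
  n <- length(samples)
  delayed <- if (d > 0) c(rep(samples[1], d), samples[seq_len(n - d)]) else samples
  with_seed(seed, delayed + rnorm(n, 0, profile$motor_noise_sd))
}

#' Define the ground-truth activation layout
#'
#' Rectangular regions inside the simulation grid, each with an activation
#' rule: `"behavior_coupled"` (Repeated-Random amplitude equals
#' `coupling_gain * weight`), `"uniform"` (the same fixed Repeated-Random
#' contrast for every subject, probing what an all-positive weight vector
#' does to uncoupled activation), or `"null"` (equal activation in both
#' conditions). Region masks must be disjoint.
#'
#' @param grid_dims Integer length-3 grid dimensions (default `c(20,20,20)`).
#' @param regions List of region specs: each a list with `name`, `rule`,
#'   `corner` (1-based), `size` (cube edge or length-3), and for uniform
#'   regions a `contrast` value. Defaults provide one coupled 7-cube, one
#'   uniform 5-cube and one null 7-cube.
#' @return A `ct_truth` object: list with `grid_dims`, `regions` and logical
#'   `masks`.
#' @export
bold_truth <- function(grid_dims = c(20, 20, 20), regions = NULL) {
  if (is.null(regions)) {
    # default layout scales with the grid; on the reference 20-cube it gives
    # a 7^3 coupled block, a 5^3 uniform block and a 7^3 null block
    g <- grid_dims
    lo <- ceiling(0.1 * g) + 1
    hi <- ceiling(0.6 * g) + 1
    big <- floor(0.35 * min(g))
    small <- floor(0.25 * min(g))
    regions <- list(
      list(name = "coupled", rule = "behavior_coupled", corner = lo,
           size = big),
      list(name = "uniform", rule = "uniform",
           corner = c(hi[1], hi[2], lo[3]), size = small, contrast = 8),
      list(name = "null", rule = "null", corner = c(hi[1], lo[2], hi[3]),
           size = big))
  }
  masks <- lapply(regions, function(r) {
    sz <- rep(r$size, length.out = 3)
    if (any(r$corner < 1) || any(r$corner + sz - 1 > grid_dims))
      stop(sprintf("region '%s' exceeds the grid", r$name), call. = FALSE)
    m <- array(FALSE, grid_dims)
    m[r$corner[1]:(r$corner[1] + sz[1] - 1),
      r$corner[2]:(r$corner[2] + sz[2] - 1),
      r$corner[3]:(r$corner[3] + sz[3] - 1)] <- TRUE
    m
  })
  names(masks) <- vapply(regions, `[[`, "", "name")
  overlap <- Reduce(`+`, lapply(masks, as.integer))
  if (any(overlap > 1L))
    stop("region masks must be disjoint", call. = FALSE)
  structure(list(grid_dims = grid_dims, regions = regions, masks = masks),
            class = "ct_truth")
}

#' Block schedule for one fMRI run
#'
#' The fixed rest/stimulation layout: 40 s rest, 150 s stimulation, 40 s
#' rest, 150 s stimulation, 40 s rest (420 s, 210 volumes at TR 2 s). Each
#' stimulation block carries a single sequence condition; the order of the
#' two conditions alternates across runs so presentation is counterbalanced
#' within a session.
#'
#' @param run_index Run number within the session (1-based).
#' @return Data frame with columns `onset_s`, `duration_s`, `condition`.
#' @export
run_block_schedule <- function(run_index = 1) {
  conds <- if (run_index %% 2 == 1) c("repeated", "random")
  else c("random", "repeated")
  data.frame(onset_s = c(40, 230), duration_s = c(150, 150),
             condition = conds, stringsAsFactors = FALSE)
}

# smooth low-amplitude motion series (cumulative drift, de-meaned)
simulate_motion <- function(n_vols, amplitude = 0.5) {
  m <- sapply(seq_len(6), function(j) {
    x <- cumsum(rnorm(n_vols, 0, amplitude / sqrt(n_vols)))
    x - mean(x)
  })
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Simulate one subject's BOLD session
#'
#' Builds `n_runs` block-design runs on the truth's grid. Every voxel time
#' series is baseline plus HRF-convolved condition boxcars scaled by the
#' voxel's condition amplitudes, a per-run linear drift, a leaked copy of
#' the motion series, and white Gaussian noise. In behavior-coupled regions
#' the Repeated-Random amplitude difference equals
#' `profile$coupling_gain * weight`; uniform regions use their fixed
#' contrast; null regions activate equally in both conditions.
#'
#' @param profile One row of [subject_profiles()].
#' @param weight The subject's behavioral difference-score weight (the
#'   quantity the coupled regions are proportional to).
#' @param truth A `ct_truth` layout from [bold_truth()].
#' @param seed Integer RNG seed.
#' @param n_runs Runs per session (default 4).
#' @param tr_s Repetition time in seconds (default 2).
#' @param run_duration_s Run length in seconds (default 420, i.e. 210
#'   volumes).
#' @param baseline Baseline signal level (default 1000).
#' @param task_amplitude Base activation amplitude in active regions
#'   (default 10, i.e. 1% of baseline).
#' @param noise_sd White-noise SD (default 15).
#' @param drift_sd SD of the per-run linear drift total excursion
#'   (default 5).
#' @param motion_amplitude Motion series amplitude (default 0.5).
#' @param motion_leak SD of the per-voxel motion leakage coefficients
#'   (default 1).
#' @return List with `runs` (list of volumes-by-voxels matrices), `motion`
#'   (list of volumes-by-6 matrices), `schedules` (list of
#'   [run_block_schedule()] tables), `tr_s`, `grid_dims`, and
#'   `true_contrast` (the programmed Repeated-Random amplitude per voxel).
#' @export
simulate_bold_session <- function(profile, weight, truth, seed = 1,
                                  n_runs = 4, tr_s = 2, run_duration_s = 420,
                                  baseline = 1000, task_amplitude = 10,
                                  noise_sd = 15, drift_sd = 5,
                                  motion_amplitude = 0.5, motion_leak = 1) {
  grid_dims <- truth$grid_dims
  nvox <- prod(grid_dims)
  n_vols <- as.integer(round(run_duration_s / tr_s))
  amp_rep <- amp_rand <- numeric(nvox)
  for (i in seq_along(truth$regions)) {
    r <- truth$regions[[i]]
    idx <- which(truth$masks[[i]])
    if (r$rule == "behavior_coupled") {
      amp_rand[idx] <- task_amplitude
      amp_rep[idx] <- task_amplitude + profile$coupling_gain * weight
    } else if (r$rule == "uniform") {
      amp_rand[idx] <- task_amplitude
      amp_rep[idx] <- task_amplitude + r$contrast
    } else {
      amp_rand[idx] <- task_amplitude
      amp_rep[idx] <- task_amplitude
    }
  }
  with_seed(seed, {
    runs <- vector("list", n_runs)
    motion <- vector("list", n_runs)
    schedules <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      sched <- run_block_schedule(r)
      schedules[[r]] <- sched
      x_rep <- hrf_regressor(sched$onset_s[sched$condition == "repeated"],
                             sched$duration_s[sched$condition == "repeated"],
                             n_vols, tr_s)
      x_rand <- hrf_regressor(sched$onset_s[sched$condition == "random"],
                              sched$duration_s[sched$condition == "random"],
                              n_vols, tr_s)
      mo <- simulate_motion(n_vols, motion_amplitude)
      gamma <- matrix(rnorm(6 * nvox, 0, motion_leak), nrow = 6)
      drift <- seq(-1, 1, length.out = n_vols) * rnorm(1, 0, drift_sd)
      Y <- matrix(rnorm(n_vols * nvox, 0, noise_sd), n_vols, nvox)
      Y <- Y + drift  # column-major recycling adds the drift to every voxel
      Y <- Y + mo %*% gamma + baseline
      act <- which(amp_rep != 0 | amp_rand != 0)  # task signal is sparse
      if (length(act))
        Y[, act] <- Y[, act] + outer(x_rep, amp_rep[act]) +
          outer(x_rand, amp_rand[act])
      runs[[r]] <- Y
      motion[[r]] <- mo
    }
    list(runs = runs, motion = motion, schedules = schedules, tr_s = tr_s,
         grid_dims = grid_dims, true_contrast = amp_rep - amp_rand)
  })
}
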