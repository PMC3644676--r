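# End-to-end recovery study on the synthetic cohort: simulate behavior on
# both scan days, estimate lag difference-score weights with the kinematics
# module, simulate coupled BOLD sessions, fit the first-level GLM, build the
# weighted group image, and measure how well the programmed ground truth is
# recovered.

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 100003 + offset) %% 2147483647)
}

#' Simulate and score one scan day of tracking behavior
#'
#' Each subject tracks `segments_per_condition` repeated-segment and as many
#' random-segment presentations; responses follow the subject's programmed
#' lag dynamics plus motor noise, and every segment is scored with
#' [score_segment()].
#'
#' @param profiles Cohort table from [subject_profiles()].
#' @param day Day number.
#' @param repeated Repeated `ct_segment`.
#' @param random_pool List of accepted random segments for this day.
#' @param seed Integer RNG seed.
#' @param segments_per_condition Presentations per condition (default 15,
#'   one scanner run's worth of 10-s segments).
#' @param max_lag_s,min_peak_r Passed to [score_segment()].
#' @return Segment score table.
#' @export
simulate_scan_day_scores <- function(profiles, day, repeated, random_pool,
                                     seed, segments_per_condition = 15,
                                     max_lag_s = 2, min_peak_r = 0.2) {
  if (length(random_pool) < segments_per_condition)
    stop("random_pool is smaller than segments_per_condition", call. = FALSE)
  rows <- list()
  k <- 0L
  for (s in seq_len(nrow(profiles))) {
    prof <- profiles[s, ]
    for (i in seq_len(segments_per_condition)) {
      for (kind in c("repeated", "random")) {
        k <- k + 1L
        tgt <- if (kind == "repeated") repeated else random_pool[[i]]
        resp <- simulate_response(tgt, prof, day, kind,
                                  seed = derive_seed(seed, k))
        rec <- tracking_record(tgt$samples, resp, tgt$sample_rate,
                               segment_kind = kind,
                               subject_id = prof$subject_id, day = day,
                               trial_index = i)
        rows[[k]] <- score_segment(rec, max_lag_s, min_peak_r)
      }
    }
  }
  do.call(rbind, rows)
}

#' End-to-end ground-truth recovery study
#'
#' Runs the whole pipeline on one simulated experiment: a seeded cohort
#' tracks on day 1 and day 7 (retention); lag difference-score weights are
#' estimated from the simulated joystick traces; BOLD sessions whose
#' behavior-coupled regions are programmed against those same weights are
#' simulated, fitted, contrasted, combined into the weighted group image for
#' each day, and thresholded. The function reports the fraction of
#' behavior-coupled voxels recovered suprathreshold on the retention day and
#' the false-positive fraction inside the null region.
#'
#' The stimulus set (repeated segment and random pool) is generated from its
#' own `stimulus_seed`, fixed by default, mirroring a study in which every
#' simulated experiment reuses one stimulus battery while subjects and noise
#' vary with `seed`.
#'
#' @param seed Integer seed for the simulated experiment (cohort, noise).
#' @param n_subjects Cohort size (default 10).
#' @param truth Ground-truth layout (default [bold_truth()] on a 20-cube).
#' @param segments_per_condition Scored segments per condition per scan day
#'   (default 15).
#' @param p_threshold Voxelwise one-sided p threshold (default 0.0005, the
#'   component-analysis threshold).
#' @param min_cluster Cluster extent threshold in voxels (default 200).
#' @param stimulus_seed Seed for the stimulus battery (default 1000).
#' @param fwhm_mm Spatial smoothing FWHM in mm applied before fitting
#'   (default 0; the seeded regions are already spatially compact).
#' @param voxel_mm Voxel size in mm (default 4).
#' @param scale_weights Weight scaling for [weight_and_sum()] (default
#'   `"rms"`, making the group statistic unit-scale under the null).
#' @param bold_args Named list of overrides for [simulate_bold_session()].
#' @return List with `coupled_coverage`, `null_fp_rate`, cluster reports
#'   `day1` and `day7`, the `weights` table, the [day_overlap()] result and
#'   the per-subject programmed (`true_diff_ms`) versus recovered
#'   (`weight`) lag differences.
#' @export
recovery_study <- function(seed, n_subjects = 10, truth = bold_truth(),
                           segments_per_condition = 15, p_threshold = 0.0005,
                           min_cluster = 200, stimulus_seed = 1000,
                           fwhm_mm = 0, voxel_mm = 4,
                           scale_weights = "rms", bold_args = list()) {
  days <- c(1, 7)
  repeated <- center_and_zero(render_segment(default_repeated_coefficients(),
                                             kind = "repeated"))
  pool <- sample_random_segments(stimulus_seed, repeated,
                                 n = segments_per_condition * length(days))
  profiles <- subject_profiles(n_subjects, seed = seed)
  grid_dims <- truth$grid_dims

  weights <- list()
  masks <- list()
  reports <- list()
  for (di in seq_along(days)) {
    day <- days[di]
    day_pool <- pool[(di - 1) * segments_per_condition +
                       seq_len(segments_per_condition)]
    scores <- simulate_scan_day_scores(profiles, day, repeated, day_pool,
                                       seed = derive_seed(seed, 7000 + day),
                                       segments_per_condition)
    ds <- difference_scores(scores, day = day, measures = "lag")
    ds <- ds[match(profiles$subject_id, ds$subject_id), ]
    weights[[di]] <- ds$weight
    contrasts <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      sess <- do.call(simulate_bold_session, c(
        list(profile = profiles[s, ], weight = ds$weight[s], truth = truth,
             seed = derive_seed(seed, 100 * day + s)), bold_args))
      bold <- do.call(rbind, sess$runs)
      if (fwhm_mm > 0) {
        arr <- array(t(bold), dim = c(grid_dims, nrow(bold)))
        arr <- smooth_volumes(arr, fwhm_mm, voxel_mm)
        bold <- t(matrix(arr, prod(grid_dims), nrow(bold)))
      }
      n_vols <- vapply(sess$runs, nrow, 1L)
      fit <- fit_glm(bold, build_design(sess$schedules, n_vols, sess$motion,
                                        sess$tr_s))
      contrasts[[s]] <- contrast_repeated_minus_random(
        fit, type = "t", grid_dims = grid_dims)$values
    }
    gimg <- weight_and_sum(contrasts, ds$weight,
                           scale_weights = scale_weights)
    reports[[di]] <- threshold_and_cluster(gimg, p_threshold, min_cluster,
                                           voxel_mm = voxel_mm)
    masks[[di]] <- reports[[di]]$mask
  }

  coupled <- truth$masks[["coupled"]]
  nullm <- truth$masks[["null"]]
  true_diff <- vapply(seq_len(n_subjects), function(s)
    lag_on_day(profiles[s, ], 7, "repeated") -
      lag_on_day(profiles[s, ], 7, "random"), numeric(1))
  list(coupled_coverage = mean(masks[[2]][coupled]),
       null_fp_rate = mean(masks[[2]][nullm]),
       day1 = reports[[1]], day7 = reports[[2]],
       weights = data.frame(subject_id = profiles$subject_id,
                            day1 = weights[[1]], day7 = weights[[2]],
                            true_diff_ms = true_diff),
       overlap = day_overlap(masks[[1]], masks[[2]]))
}
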