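# End-to-end orchestration: stimuli -> behavior -> summary -> GLM -> group
# maps, driven by one configuration list, with a manifest recording the
# config snapshot, seeds, stage status and a checksum for every output file.

pipeline_stages <- c("stimuli", "behavior", "summary", "glm", "group")

record_file <- function(manifest, path) {
  manifest$files[[basename(path)]] <- unname(tools::md5sum(path))
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order under a single configuration
#' (see [default_config()]):
#'
#' 1. **stimuli** — repeated segment, counterbalanced practice schedules and
#'    the screened random-segment pools; target trajectory tables.
#' 2. **behavior** — simulated joystick responses for every subject, day and
#'    segment; kinematic score table.
#' 3. **summary** — per-day lag/rmse/spatial difference scores for the scan
#'    days, day-by-sequence repeated-measures ANOVA over the practice days,
#'    and a simulated explicit-recognition report.
#' 4. **glm** — per subject and scan day: simulated BOLD session, optional
#'    spatial smoothing, GLM fit, Repeated-Random t contrast (NIfTI).
#' 5. **group** — behaviorally weighted group image, cluster report and
#'    day-1/day-7 overlap for each of the three measures.
#'
#' A stage failure is recorded in the manifest and the remaining stages are
#' skipped.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param write_bold Also write every simulated BOLD run as NIfTI (large;
#'   default `FALSE`).
#' @return The manifest (invisibly): config snapshot, per-stage status and
#'   timings, and md5 checksums of every written file. Also written to
#'   `manifest.yaml` in `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         write_bold = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, stages = list(), files = list())
  seed <- config$seed
  state <- new.env(parent = emptyenv())
  for (stage in pipeline_stages) {
    t0 <- Sys.time()
    res <- tryCatch({
      manifest <- switch(stage,
        stimuli = stage_stimuli(config, out_dir, state, manifest),
        behavior = stage_behavior(config, out_dir, state, manifest),
        summary = stage_summary(config, out_dir, state, manifest),
        glm = stage_glm(config, out_dir, state, manifest, write_bold),
        group = stage_group(config, out_dir, state, manifest))
      list(status = "ok")
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    res$seconds <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    manifest$stages[[stage]] <- res
    if (res$status == "failed") {
      message(sprintf("stage '%s' failed: %s; downstream stages skipped",
                      stage, res$error))
      break
    }
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

stage_stimuli <- function(config, out_dir, state, manifest) {
  st <- config$stimulus
  sch <- config$schedule
  repeated <- center_and_zero(render_segment(
    unlist(st$repeated_coefficients), st$duration_s, st$sample_rate,
    kind = "repeated"))
  state$repeated <- repeated
  all_days <- sort(c(sch$practice_days, sch$scan_days))
  state$days <- all_days
  state$schedule <- build_schedule(sch$trials_per_day, sch$block_size,
                                   n_days = length(sch$practice_days),
                                   seed = derive_seed(config$seed, 1))
  state$schedule$day <- sch$practice_days[state$schedule$day]
  # one screened random segment per practice trial, plus the scan pools;
  # shared by all subjects
  n_practice <- nrow(state$schedule)
  n_scan <- config$bold$scan_segments_per_condition * length(sch$scan_days)
  pool <- sample_random_segments(
    derive_seed(config$seed, 2), repeated, n = n_practice + n_scan,
    coefficient_range = st$coefficient_range, limit_deg = st$limit_deg,
    rom_tolerance = st$rom_tolerance,
    velocity_floor_frac = st$velocity_floor_frac,
    slope_tolerance = st$slope_tolerance)
  state$practice_pool <- pool[seq_len(n_practice)]
  state$scan_pools <- split(pool[n_practice + seq_len(n_scan)],
                            rep(seq_along(sch$scan_days),
                                each = config$bold$scan_segments_per_condition))
  # target trajectory tables, one per practice day
  rate <- st$sample_rate
  nsamp <- length(repeated$samples)
  for (d in sch$practice_days) {
    dsch <- state$schedule[state$schedule$day == d, ]
    rows <- lapply(seq_len(nrow(dsch)), function(i) {
      tr <- dsch[i, ]
      rseg <- state$practice_pool[[which(state$schedule$day == d)[i]]]
      first_rep <- tr$order_flag == "repeated_first"
      segs <- if (first_rep) list(repeated, rseg) else list(rseg, repeated)
      do.call(rbind, lapply(1:2, function(j) data.frame(
        time_s = ((tr$trial - 1) * 2 * nsamp + (j - 1) * nsamp +
                    seq_len(nsamp) - 1) / rate,
        angle_deg = segs[[j]]$samples, segment_kind = segs[[j]]$kind,
        trial_index = tr$trial, segment_index = j)))
    })
    path <- file.path(out_dir, sprintf("targets_day%d.tsv", d))
    write_trajectory(do.call(rbind, rows), path)
    manifest <- record_file(manifest, path)
  }
  manifest
}

stage_behavior <- function(config, out_dir, state, manifest) {
  sch <- config$schedule
  profiles <- subject_profiles(
    config$cohort$n_subjects, seed = derive_seed(config$seed, 3),
    baseline_lag_ms = config$cohort$baseline_lag_ms,
    baseline_lag_sd = config$cohort$baseline_lag_sd,
    rate_repeated = config$cohort$rate_repeated,
    rate_repeated_sd = config$cohort$rate_repeated_sd,
    rate_random = config$cohort$rate_random,
    rate_random_sd = config$cohort$rate_random_sd,
    motor_noise_sd = config$cohort$motor_noise_sd,
    coupling_gain = config$cohort$coupling_gain)
  state$profiles <- profiles
  scores <- list()
  k <- 0L
  # practice days: the scheduled trials
  for (d in sch$practice_days) {
    dsch <- state$schedule[state$schedule$day == d, ]
    idx <- which(state$schedule$day == d)
    for (s in seq_len(nrow(profiles))) {
      prof <- profiles[s, ]
      for (i in seq_len(nrow(dsch))) {
        rseg <- state$practice_pool[[idx[i]]]
        for (seg in list(state$repeated, rseg)) {
          k <- k + 1L
          resp <- simulate_response(seg, prof, d, seg$kind,
                                    seed = derive_seed(config$seed, 10000 + k))
          rec <- tracking_record(seg$samples, resp, seg$sample_rate,
                                 segment_kind = seg$kind,
                                 subject_id = prof$subject_id, day = d,
                                 trial_index = dsch$trial[i])
          scores[[k]] <- score_segment(rec, config$analysis$max_lag_s,
                                       config$analysis$min_peak_r)
        }
      }
    }
  }
  practice_scores <- if (k > 0) do.call(rbind, scores) else NULL
  # scan days: block presentations
  scan_scores <- do.call(rbind, lapply(seq_along(sch$scan_days), function(di) {
    simulate_scan_day_scores(
      profiles, sch$scan_days[di], state$repeated, state$scan_pools[[di]],
      seed = derive_seed(config$seed, 20000 + di),
      segments_per_condition = config$bold$scan_segments_per_condition,
      max_lag_s = config$analysis$max_lag_s,
      min_peak_r = config$analysis$min_peak_r)
  }))
  state$scores <- rbind(practice_scores, scan_scores)
  path <- file.path(out_dir, "segment_scores.tsv")
  write_scores(state$scores, path)
  record_file(manifest, path)
}

stage_summary <- function(config, out_dir, state, manifest) {
  sch <- config$schedule
  # difference scores and weights per scan day
  ds <- do.call(rbind, lapply(sch$scan_days, function(d) {
    out <- difference_scores(state$scores, day = d)
    out$day <- d
    out
  }))
  state$diff_scores <- ds
  path <- file.path(out_dir, "difference_scores.tsv")
  write.table(ds, path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- record_file(manifest, path)
  # day x sequence ANOVA over the practice days, per measure
  anova_rows <- do.call(rbind, lapply(c("rmse", "lag", "spatial"), function(m) {
    col <- measure_column(m)
    pr <- state$scores[state$scores$day %in% sch$practice_days, ]
    cells <- aggregate(pr[[col]],
                       by = list(subject = pr$subject_id, day = pr$day,
                                 sequence = pr$segment_kind), FUN = mean)
    names(cells)[4] <- "value"
    res <- rm_anova(cells)
    res$measure <- m
    res
  }))
  path <- file.path(out_dir, "practice_anova.tsv")
  write.table(anova_rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- record_file(manifest, path)
  # explicit recognition: judgments at chance (no explicit knowledge in the
  # simulated cohort)
  rec <- with_seed(derive_seed(config$seed, 4), {
    do.call(rbind, lapply(state$profiles$subject_id, function(sid) {
      truth <- sample(c(rep(TRUE, 3), rep(FALSE, 7)))
      ans <- runif(10) < 0.5
      r <- score_recognition(truth, ans)
      data.frame(subject_id = sid, hits = r$hits,
                 correct_rejections = r$correct_rejections,
                 percent_correct = r$percent_correct, explicit = r$explicit)
    }))
  })
  state$recognition <- rec
  path <- file.path(out_dir, "recognition.tsv")
  write.table(rec, path, sep = "\t", row.names = FALSE, quote = FALSE)
  record_file(manifest, path)
}

stage_glm <- function(config, out_dir, state, manifest, write_bold) {
  bd <- config$bold
  truth <- bold_truth(bd$grid_dims)
  state$truth <- truth
  state$contrasts <- list()
  for (d in config$schedule$scan_days) {
    lagw <- state$diff_scores[state$diff_scores$day == d &
                                state$diff_scores$measure == "lag", ]
    day_contrasts <- vector("list", nrow(state$profiles))
    for (s in seq_len(nrow(state$profiles))) {
      w <- lagw$weight[match(state$profiles$subject_id[s], lagw$subject_id)]
      sess <- simulate_bold_session(
        state$profiles[s, ], w, truth,
        seed = derive_seed(config$seed, 30000 + 100 * d + s),
        n_runs = bd$n_runs, tr_s = bd$tr_s,
        run_duration_s = bd$run_duration_s, baseline = bd$baseline,
        task_amplitude = bd$task_amplitude, noise_sd = bd$noise_sd,
        drift_sd = bd$drift_sd, motion_amplitude = bd$motion_amplitude,
        motion_leak = bd$motion_leak)
      if (write_bold) for (r in seq_along(sess$runs)) {
        path <- file.path(out_dir, sprintf("bold_sub%02d_day%d_run%d.nii.gz",
                                           s, d, r))
        write_bold_nifti(sess$runs[[r]], bd$grid_dims, path, bd$voxel_mm,
                         bd$tr_s)
        manifest <- record_file(manifest, path)
      }
      bold <- do.call(rbind, sess$runs)
      if (config$analysis$fwhm_mm > 0) {
        arr <- array(t(bold), dim = c(bd$grid_dims, nrow(bold)))
        arr <- smooth_volumes(arr, config$analysis$fwhm_mm, bd$voxel_mm)
        bold <- t(matrix(arr, prod(bd$grid_dims), nrow(bold)))
      }
      fit <- fit_glm(bold, build_design(sess$schedules,
                                        vapply(sess$runs, nrow, 1L),
                                        sess$motion, bd$tr_s))
      con <- contrast_repeated_minus_random(
        fit, type = config$analysis$contrast_type, grid_dims = bd$grid_dims)
      day_contrasts[[s]] <- con$values
      path <- file.path(out_dir, sprintf("contrast_sub%02d_day%d.nii.gz", s, d))
      write_stat_nifti(con$values, path, bd$voxel_mm)
      manifest <- record_file(manifest, path)
    }
    state$contrasts[[as.character(d)]] <- day_contrasts
  }
  manifest
}

stage_group <- function(config, out_dir, state, manifest) {
  an <- config$analysis
  masks <- list()
  for (m in c("rmse", "lag", "spatial")) {
    p_thr <- if (m == "rmse") an$rmse_p_threshold else an$component_p_threshold
    for (d in config$schedule$scan_days) {
      dsm <- state$diff_scores[state$diff_scores$day == d &
                                 state$diff_scores$measure == m, ]
      w <- dsm$weight[match(state$profiles$subject_id, dsm$subject_id)]
      img <- weight_and_sum(state$contrasts[[as.character(d)]], w,
                            center_weights = isTRUE(an$center_weights),
                            scale_weights = an$scale_weights)
      rep_ <- threshold_and_cluster(img, p_thr, an$min_cluster,
                                    an$connectivity, config$bold$voxel_mm)
      masks[[sprintf("%s_day%d", m, d)]] <- rep_$mask
      path <- file.path(out_dir, sprintf("group_%s_day%d.nii.gz", m, d))
      write_stat_nifti(img, path, config$bold$voxel_mm)
      manifest <- record_file(manifest, path)
      path <- file.path(out_dir, sprintf("clusters_%s_day%d.tsv", m, d))
      write.table(rep_$report, path, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      manifest <- record_file(manifest, path)
    }
    days <- config$schedule$scan_days
    if (length(days) == 2) {
      ov <- day_overlap(masks[[sprintf("%s_day%d", m, days[1])]],
                        masks[[sprintf("%s_day%d", m, days[2])]])
      path <- file.path(out_dir, sprintf("overlap_%s.tsv", m))
      write.table(data.frame(measure = m, n_overlap = ov$n_overlap,
                             n_learning_specific = ov$n_learning_specific),
                  path, sep = "\t", row.names = FALSE, quote = FALSE)
      manifest <- record_file(manifest, path)
    }
  }
  manifest
}
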