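# File formats: trajectory and score tables (TSV), BOLD volumes (NIfTI),
# structured-text config and manifests (YAML).

#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline in one nested list:
#' stimulus generation (durations, screens, the repeated-segment
#' coefficients), cohort simulation (subject dynamics, BOLD geometry and
#' noise), analysis settings (lag window, smoothing, thresholds) and seeds.
#' The defaults describe the reference study design: 10 subjects, 7 days
#' (5 practice days of 50 trials between two scan days), 4 runs of 210
#' volumes at TR 2 s per scan day, 20x20x20 simulation grid.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    stimulus = list(duration_s = 10, sample_rate = 50,
                    rom_tolerance = 0.05, velocity_floor_frac = 0.8,
                    slope_tolerance = 0.20, coefficient_range = c(-10, 10),
                    limit_deg = 20,
                    repeated_coefficients = as.list(default_repeated_coefficients())),
    schedule = list(practice_days = 2:6, scan_days = c(1, 7),
                    trials_per_day = 50, block_size = 10),
    cohort = list(n_subjects = 10, baseline_lag_ms = -300,
                  baseline_lag_sd = 30, rate_repeated = 0.4,
                  rate_repeated_sd = 0.08, rate_random = 0.1,
                  rate_random_sd = 0.04, motor_noise_sd = 1,
                  coupling_gain = 0.05),
    bold = list(grid_dims = c(20, 20, 20), n_runs = 4, tr_s = 2,
                run_duration_s = 420, baseline = 1000, task_amplitude = 10,
                noise_sd = 15, drift_sd = 5, motion_amplitude = 0.5,
                motion_leak = 1, voxel_mm = 4,
                scan_segments_per_condition = 15),
    analysis = list(max_lag_s = 2, min_peak_r = 0.2, fwhm_mm = 4,
                    contrast_type = "t",
                    rmse_p_threshold = 0.005,
                    component_p_threshold = 0.0005,
                    min_cluster = 200, connectivity = 6,
                    center_weights = FALSE, scale_weights = "rms"))
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the [default_config()] structure; missing fields are
#' filled from the defaults.
#'
#' @param path File path.
#' @param config Configuration list.
#' @return `read_config()` returns the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Write / read a trajectory table
#'
#' Tab-separated samples with columns `time_s`, `angle_deg`,
#' `segment_kind`, `trial_index`, `segment_index`.
#'
#' @param df Trajectory data frame.
#' @param path File path (`.tsv`).
#' @return `read_trajectory()` returns the data frame.
#' @export
write_trajectory <- function(df, path) {
  need <- c("time_s", "angle_deg", "segment_kind", "trial_index",
            "segment_index")
  if (!all(need %in% names(df)))
    stop("trajectory table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  write.table(df[, need], path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write / read a segment score table
#'
#' @param scores Score table from [score_records()].
#' @param path File path (`.tsv`).
#' @return `read_scores()` returns the data frame.
#' @export
write_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write / read BOLD volumes as NIfTI
#'
#' A volumes-by-voxels run matrix is reshaped onto its 3D grid (time last)
#' and written as a single-file NIfTI volume with the voxel size and TR in
#' `pixdim`.
#'
#' @param run Volumes-by-voxels matrix (or 3D/4D array).
#' @param grid_dims Length-3 grid dimensions.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_mm Voxel edge length in mm (default 4).
#' @param tr_s Repetition time in seconds (default 2).
#' @return `read_bold_nifti()` returns a list with `data` (volumes x
#'   voxels), `grid_dims`, `voxel_mm`, `tr_s`.
#' @export
write_bold_nifti <- function(run, grid_dims, path, voxel_mm = 4, tr_s = 2) {
  arr <- if (is.matrix(run))
    array(t(run), dim = c(grid_dims, nrow(run)))
  else run
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(voxel_mm, 3), tr_s)[seq_len(length(dim(arr)))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  pd <- RNifti::pixdim(img)
  if (length(d) == 4L) {
    data <- t(matrix(arr, prod(d[1:3]), d[4]))
    grid <- d[1:3]
  } else {
    data <- matrix(as.numeric(arr), 1)
    grid <- d
  }
  list(data = data, grid_dims = grid, voxel_mm = pd[1],
       tr_s = if (length(pd) >= 4) pd[4] else NA_real_)
}

#' Write a 3D statistic image as NIfTI
#'
#' @param img 3D array (e.g. a contrast or group image).
#' @param path Output path.
#' @param voxel_mm Voxel edge length in mm (default 4).
#' @return The path, invisibly.
#' @export
write_stat_nifti <- function(img, path, voxel_mm = 4) {
  arr <- array(as.numeric(img), dim = dim(img))
  out <- RNifti::asNifti(arr)
  RNifti::pixdim(out) <- rep(voxel_mm, 3)
  RNifti::writeNifti(out, path)
  invisible(path)
}
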