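# Per-subject block-design GLM: HRF-convolved condition boxcars plus motion
# and per-run baseline/drift nuisance regressors, ordinary least squares per
# voxel, and the Repeated-Random contrast image.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a response peaking near `peak` seconds
#' and an undershoot peaking near `undershoot` seconds scaled by `ratio`,
#' normalized to unit peak height.
#'
#' @param t Time points in seconds.
#' @param peak Response gamma shape (peak time in s for rate 1; default 6).
#' @param undershoot Undershoot gamma shape (default 16).
#' @param ratio Undershoot amplitude relative to the response (default 1/6).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- dgamma(t, shape = peak, rate = 1) -
    ratio * dgamma(t, shape = undershoot, rate = 1)
  tt <- seq(0, 32, by = 0.01)
  mx <- max(dgamma(tt, shape = peak, rate = 1) -
              ratio * dgamma(tt, shape = undershoot, rate = 1))
  h / mx
}

#' HRF-convolved boxcar regressor
#'
#' Builds the condition boxcar at a fine temporal grid, convolves it with
#' the canonical HRF, and samples the result at volume acquisition times.
#' Zero during rest (up to the hemodynamic tail following stimulation).
#'
#' @param onsets_s Stimulation onsets in seconds.
#' @param durations_s Stimulation durations in seconds (recycled).
#' @param n_vols Number of volumes in the run.
#' @param tr_s Repetition time in seconds.
#' @param dt Fine-grid resolution for the convolution (default 0.1 s).
#' @param ... Passed to [canonical_hrf()].
#' @return Numeric regressor of length `n_vols`.
#' @export
hrf_regressor <- function(onsets_s, durations_s, n_vols, tr_s, dt = 0.1, ...) {
  if (length(onsets_s) == 0) return(numeric(n_vols))
  durations_s <- rep(durations_s, length.out = length(onsets_s))
  total_s <- n_vols * tr_s
  tt <- seq(0, total_s, by = dt)
  box <- numeric(length(tt))
  for (i in seq_along(onsets_s))
    box[tt >= onsets_s[i] & tt < onsets_s[i] + durations_s[i]] <- 1
  kern <- canonical_hrf(seq(0, 32, by = dt), ...)
  conv <- convolve(box, rev(kern), type = "open")[seq_along(tt)] * dt
  conv <- conv / max(conv)  # unit peak so betas are in signal units
  conv[abs(conv) < 1e-12] <- 0  # clamp FFT round-off so rest stays exactly 0
  vol_t <- (seq_len(n_vols) - 1) * tr_s
  conv[pmin(round(vol_t / dt) + 1, length(conv))]
}

#' Build the concatenated-session design matrix
#'
#' Columns: the two HRF-convolved condition regressors (`task_repeated`,
#' `task_random`) spanning all runs, the six motion parameters, and a
#' per-run baseline and linear-drift pair (2 + 6 + 2 x runs columns in
#' total). Task regressors are zero during rest.
#'
#' @param schedules List (one per run) of block schedules with columns
#'   `onset_s`, `duration_s`, `condition` (see [run_block_schedule()]).
#' @param n_vols Volumes per run: a single value or one per run.
#' @param motion List (one per run) of volumes-by-6 motion parameter
#'   matrices.
#' @param tr_s Repetition time in seconds (default 2).
#' @return Design matrix with `n_vols` summed rows; attributes `runs`
#'   (per-run row counts) and `tr_s`.
#' @export
build_design <- function(schedules, n_vols, motion, tr_s = 2) {
  n_runs <- length(schedules)
  n_vols <- rep(n_vols, length.out = n_runs)
  if (length(motion) != n_runs)
    stop("`motion` must supply one matrix per run", call. = FALSE)
  for (r in seq_len(n_runs)) {
    if (nrow(motion[[r]]) != n_vols[r] || ncol(motion[[r]]) != 6L)
      stop(sprintf("motion table for run %d must be %d x 6", r, n_vols[r]),
           call. = FALSE)
  }
  total <- sum(n_vols)
  task <- matrix(0, total, 2, dimnames = list(NULL, c("task_repeated", "task_random")))
  base <- matrix(0, total, 2 * n_runs)
  colnames(base) <- paste0(rep(paste0("run", seq_len(n_runs)), each = 2),
                           c("_mean", "_drift"))
  offset <- 0L
  for (r in seq_len(n_runs)) {
    rows <- offset + seq_len(n_vols[r])
    sch <- schedules[[r]]
    for (cond in c("repeated", "random")) {
      sel <- sch$condition == cond
      if (any(sel))
        task[rows, paste0("task_", cond)] <-
          hrf_regressor(sch$onset_s[sel], sch$duration_s[sel], n_vols[r], tr_s)
    }
    base[rows, 2 * r - 1] <- 1
    base[rows, 2 * r] <- seq(-1, 1, length.out = n_vols[r])
    offset <- offset + n_vols[r]
  }
  mo <- do.call(rbind, motion)
  colnames(mo) <- paste0("motion", 1:6)
  X <- cbind(task, mo, base)
  attr(X, "runs") <- n_vols
  attr(X, "tr_s") <- tr_s
  X
}

#' Fit the voxelwise GLM by ordinary least squares
#'
#' @param bold Volumes-by-voxels data matrix (concatenated runs), or a list
#'   of per-run matrices which are row-bound.
#' @param design Design matrix from [build_design()].
#' @return A `ct_glm_fit`: list with `beta` (coefficients x voxels),
#'   `sigma2` (residual variance per voxel), `df` (residual degrees of
#'   freedom), `xtx_inv`, and `columns`.
#' @export
fit_glm <- function(bold, design) {
  if (is.list(bold)) bold <- do.call(rbind, bold)
  if (nrow(bold) != nrow(design))
    stop("data and design row counts differ", call. = FALSE)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[seq.int(qrX$rank + 1, ncol(design))]]
    stop(sprintf("design matrix is rank deficient; aliased columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrX, bold)
  res <- bold - design %*% beta
  df <- nrow(design) - ncol(design)
  mu <- colMeans(bold)
  ms_total <- colMeans(bold^2) - mu^2
  structure(list(beta = beta, sigma2 = colSums(res^2) / df, df = df,
                 xtx_inv = chol2inv(chol(crossprod(design))),
                 columns = colnames(design), ms_total = ms_total),
            class = "ct_glm_fit")
}

#' Repeated minus Random contrast image
#'
#' Applies the contrast `c = [+1 (task_repeated), -1 (task_random), 0 ...]`
#' to a fitted GLM. By default a t-statistic image,
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)`; `type = "beta"` returns the
#' raw amplitude difference instead. Voxels with zero residual variance
#' (infinite t) are capped at the largest finite |t| and flagged.
#'
#' @param fit A `ct_glm_fit`.
#' @param type `"t"` (default) or `"beta"`.
#' @param grid_dims Optional length-3 dims; when given the image is returned
#'   as a 3D array.
#' @return A `ct_contrast`: list with `values` (vector or 3D array), `type`
#'   and logical `capped` marking zero-variance voxels.
#' @export
contrast_repeated_minus_random <- function(fit, type = c("t", "beta"),
                                           grid_dims = NULL) {
  type <- match.arg(type)
  cvec <- as.numeric(fit$columns == "task_repeated") -
    as.numeric(fit$columns == "task_random")
  effect <- drop(crossprod(cvec, fit$beta))
  if (type == "beta") {
    vals <- effect
    capped <- rep(FALSE, length(effect))
  } else {
    cXc <- drop(crossprod(cvec, fit$xtx_inv %*% cvec))
    se <- sqrt(fit$sigma2 * cXc)
    # zero residual variance, judged relative to each voxel's total variance
    capped <- fit$sigma2 <= 1e-16 * pmax(fit$ms_total, .Machine$double.eps)
    vals <- ifelse(capped, 0, effect / ifelse(se == 0, 1, se))
    if (any(capped)) {
      cap <- if (all(capped)) 1e6 else max(abs(vals[!capped]))
      vals[capped] <- sign(effect[capped]) * cap
    }
  }
  if (!is.null(grid_dims)) {
    vals <- array(vals, grid_dims)
    capped <- array(capped, grid_dims)
  }
  structure(list(values = vals, type = type, capped = capped),
            class = "ct_contrast")
}

# truncated discrete Gaussian kernel as an n x n banded matrix with
# edge-renormalized rows (so constants are preserved)
gaussian_axis_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

apply_axis <- function(x, K, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  m <- K %*% matrix(xp, nrow = d[axis])
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

#' Gaussian spatial smoothing of image volumes
#'
#' Separable 3D Gaussian smoothing with kernel standard deviation
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis, applied to a 3D volume or to
#' every volume of a 4D series. Kernels are truncated at 4 sigma and
#' renormalized, so constant images are preserved exactly. `fwhm_mm = 0`
#' returns the input unchanged.
#'
#' @param x 3D or 4D numeric array.
#' @param fwhm_mm Full width at half maximum in mm.
#' @param voxel_mm Voxel edge length in mm, scalar or per-axis (default 4).
#' @return Smoothed array of the same shape.
#' @export
smooth_volumes <- function(x, fwhm_mm, voxel_mm = 4) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be non-negative", call. = FALSE)
  if (fwhm_mm == 0) return(x)
  d <- dim(x)
  if (!length(d) %in% c(3L, 4L))
    stop("`x` must be a 3D or 4D array", call. = FALSE)
  voxel_mm <- rep(voxel_mm, length.out = 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  for (axis in 1:3)
    x <- apply_axis(x, gaussian_axis_matrix(d[axis], sigma_vox[axis]), axis)
  x
}
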