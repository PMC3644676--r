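# Kinematic decomposition of tracking performance.
#
# Each scored segment yields: overall tracking error (RMSE between target and
# response), temporal precision (the signed time lag at which the
# target-response cross-correlation peaks; negative = response trails the
# target), spatial accuracy (squared correlation at the best lag), and
# spatial error (RMSE after shifting out the lag).

#' Construct a tracking record
#'
#' Pairs one segment's target and response sample streams with its metadata.
#'
#' @param target Target angle samples (degrees).
#' @param response Response angle samples (degrees), same length.
#' @param sample_rate Sampling rate in Hz (default 50).
#' @param segment_kind `"repeated"` or `"random"` (optional).
#' @param subject_id,day,trial_index Optional identifiers carried through to
#'   score tables.
#' @return A `ct_record` object.
#' @export
tracking_record <- function(target, response, sample_rate = 50,
                            segment_kind = NA_character_,
                            subject_id = NA, day = NA, trial_index = NA) {
  check_finite(target, "target")
  check_finite(response, "response")
  if (length(target) != length(response))
    stop("`target` and `response` must have equal length", call. = FALSE)
  if (length(target) < 2L)
    stop("streams must contain at least 2 samples", call. = FALSE)
  check_scalar(sample_rate, "sample_rate", 0, strict = TRUE)
  structure(list(target = as.numeric(target),
                 response = as.numeric(response),
                 sample_rate = sample_rate, segment_kind = segment_kind,
                 subject_id = subject_id, day = day,
                 trial_index = trial_index),
            class = "ct_record")
}

#' Overall tracking error (RMSE)
#'
#' Root-mean-square deviation between response and target angles, in degrees.
#'
#' @param record A `ct_record`.
#' @return RMSE in degrees.
#' @export
tracking_rmse <- function(record) {
  sqrt(mean((record$response - record$target)^2))
}

# Overlap-only Pearson correlation of target vs response advanced by each
# integer shift s in -L..L. `direct` loops with cor(); `fft` computes all
# cross-products at once via convolve() and the per-shift means/variances
# from cumulative sums -- identical up to FFT round-off.
shift_correlations <- function(target, response, max_shift,
                               method = c("fft", "direct")) {
  method <- match.arg(method)
  n <- length(target)
  L <- max_shift
  shifts <- -L:L
  if (method == "direct") {
    cors <- vapply(shifts, function(s) {
      if (s >= 0) {
        t_ <- target[seq_len(n - s)]
        r_ <- response[seq.int(1 + s, n)]
      } else {
        t_ <- target[seq.int(1 - s, n)]
        r_ <- response[seq_len(n + s)]
      }
      if (sd(t_) == 0 || sd(r_) == 0) return(NA_real_)
      cor(t_, r_)
    }, numeric(1))
    return(setNames(cors, shifts))
  }
  # cross[s] = sum_i target[i] * response[i + s]
  cross <- convolve(response, target, conj = TRUE, type = "open")[shifts + n]
  cs_t <- cumsum(target); cs_t2 <- cumsum(target^2)
  cs_r <- cumsum(response); cs_r2 <- cumsum(response^2)
  m <- n - abs(shifts)
  # overlap sums for target: indices 1..n-s (s>=0) or 1-s..n (s<0)
  st <- ifelse(shifts >= 0, cs_t[m], cs_t[n] - cs_t[pmax(-shifts, 1)])
  st2 <- ifelse(shifts >= 0, cs_t2[m], cs_t2[n] - cs_t2[pmax(-shifts, 1)])
  sr <- ifelse(shifts >= 0, cs_r[n] - c(0, cs_r)[pmax(shifts, 0) + 1], cs_r[m])
  sr2 <- ifelse(shifts >= 0, cs_r2[n] - c(0, cs_r2)[pmax(shifts, 0) + 1], cs_r2[m])
  vt <- st2 - st^2 / m
  vr <- sr2 - sr^2 / m
  cov <- cross - st * sr / m
  scale_t <- pmax(st2, 1)  # tolerance scale for zero-variance detection
  scale_r <- pmax(sr2, 1)
  bad <- vt <= 1e-12 * scale_t | vr <= 1e-12 * scale_r
  cors <- ifelse(bad, NA_real_, cov / sqrt(pmax(vt, 0) * pmax(vr, 0)))
  setNames(pmin(pmax(cors, -1), 1), shifts)
}

#' Estimate tracking time lag and spatial accuracy
#'
#' Slides the response relative to the target over integer-sample shifts in
#' `[-max_lag_s, +max_lag_s]`, computing the Pearson correlation over only
#' the continuously overlapping portion at each shift (re-centred per shift;
#' no padding). The shift maximizing the squared correlation gives the time
#' lag; ties are broken toward the smallest absolute shift (favouring the
#' null of no lag). The lag is reported in milliseconds and is negative when
#' the response trails the target.
#'
#' @param record A `ct_record`.
#' @param max_lag_s Half-width of the lag search window in seconds
#'   (default 2).
#' @param method `"fft"` (default, exact up to round-off) or `"direct"`
#'   (explicit per-shift loop; used as a cross-check).
#' @return List with `lag_ms`, `lag_samples` (same sign convention), `r2`,
#'   `peak_cor`, `anticorrelated` (peak correlation negative) and
#'   `degenerate` (no shift had a defined correlation).
#' @export
#' @examples
#' tgt <- sin(seq(0, 2 * pi, length.out = 500))
#' rec <- tracking_record(tgt, c(rep(0, 5), tgt[1:495]))
#' estimate_lag(rec)$lag_ms  # -100
estimate_lag <- function(record, max_lag_s = 2, method = c("fft", "direct")) {
  n <- length(record$target)
  L <- floor(max_lag_s * record$sample_rate)
  if (L >= n / 2)
    stop("`max_lag_s` times the sample rate must be below half the stream length",
         call. = FALSE)
  cors <- shift_correlations(record$target, record$response, L, match.arg(method))
  shifts <- -L:L
  if (all(is.na(cors)))
    return(list(lag_ms = NA_real_, lag_samples = NA_real_, r2 = NA_real_,
                peak_cor = NA_real_, anticorrelated = NA, degenerate = TRUE))
  r2 <- cors^2
  best <- max(r2, na.rm = TRUE)
  cand <- which(!is.na(r2) & r2 >= best - 1e-10)
  pick <- cand[order(abs(shifts[cand]), shifts[cand])][1]
  s <- shifts[pick]
  list(lag_ms = -s * 1000 / record$sample_rate,
       lag_samples = -s,
       r2 = unname(r2[pick]),
       peak_cor = unname(cors[pick]),
       anticorrelated = unname(cors[pick] < 0),
       degenerate = FALSE)
}

#' Lag-corrected spatial tracking error
#'
#' RMSE computed after shifting the response by the (negated) lag so that
#' target and response are temporally aligned; only the overlapping region
#' contributes. With `lag_samples = 0` this reduces to [tracking_rmse()].
#'
#' @param record A `ct_record`.
#' @param lag_samples Signed lag in samples as returned by [estimate_lag()]
#'   (negative when the response trails the target).
#' @param min_overlap_s Minimum admissible overlap in seconds (default 1);
#'   shorter overlaps return `NA` with a warning attribute.
#' @return Spatial error in degrees (`NA` if the overlap is too short, with
#'   attribute `flag = "short_overlap"`).
#' @export
spatial_error <- function(record, lag_samples, min_overlap_s = 1) {
  n <- length(record$target)
  a <- as.integer(round(-lag_samples))  # samples to advance the response
  if (abs(a) >= n)
    stop("lag exceeds stream length", call. = FALSE)
  if (a >= 0) {
    t_ <- record$target[seq_len(n - a)]
    r_ <- record$response[seq.int(1 + a, n)]
  } else {
    t_ <- record$target[seq.int(1 - a, n)]
    r_ <- record$response[seq_len(n + a)]
  }
  if (length(t_) < min_overlap_s * record$sample_rate)
    return(structure(NA_real_, flag = "short_overlap"))
  sqrt(mean((r_ - t_)^2))
}

#' Score one tracked segment
#'
#' Bundles [tracking_rmse()], [estimate_lag()] and [spatial_error()] into a
#' one-row data frame. The lag is flagged unreliable when the peak
#' correlation magnitude falls below `min_peak_r`.
#'
#' @param record A `ct_record`.
#' @param max_lag_s Lag search half-window in seconds.
#' @param min_peak_r Reliability floor on the peak correlation magnitude
#'   (default 0.2).
#' @return Data frame with columns `subject_id`, `day`, `trial_index`,
#'   `segment_kind`, `rmse`, `lag_ms`, `r2`, `spatial_rmse`,
#'   `lag_unreliable`, `anticorrelated`, `degenerate`.
#' @export
score_segment <- function(record, max_lag_s = 2, min_peak_r = 0.2) {
  rmse <- tracking_rmse(record)
  lag <- estimate_lag(record, max_lag_s)
  sp <- if (lag$degenerate) NA_real_ else
    spatial_error(record, lag$lag_samples)
  data.frame(subject_id = record$subject_id, day = record$day,
             trial_index = record$trial_index,
             segment_kind = record$segment_kind,
             rmse = rmse, lag_ms = lag$lag_ms, r2 = lag$r2,
             spatial_rmse = as.numeric(sp),
             lag_unreliable = isTRUE(lag$degenerate) ||
               (!is.na(lag$peak_cor) && abs(lag$peak_cor) < min_peak_r),
             anticorrelated = isTRUE(lag$anticorrelated),
             degenerate = isTRUE(lag$degenerate),
             stringsAsFactors = FALSE)
}

#' Score a list of tracking records
#'
#' @param records List of `ct_record` objects.
#' @inheritParams score_segment
#' @return Row-bound data frame of [score_segment()] results.
#' @export
score_records <- function(records, max_lag_s = 2, min_peak_r = 0.2) {
  do.call(rbind, lapply(records, score_segment, max_lag_s = max_lag_s,
                        min_peak_r = min_peak_r))
}
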