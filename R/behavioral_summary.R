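# Aggregation of segment scores into sequence-specific difference scores,
# outlier removal, the day-by-sequence repeated-measures ANOVA, and
# explicit-recognition scoring.

measure_column <- function(measure) {
  switch(measure,
         rmse = "rmse", lag = "lag_ms", spatial = "spatial_rmse",
         stop(sprintf("unknown measure '%s'", measure), call. = FALSE))
}

#' Sequence-specific difference scores
#'
#' For each subject and measure, the mean over that day's repeated segments
#' minus the mean over its random segments. The statistical weight carries
#' the convention that a positive value always means a sequence-specific
#' advantage: for the error measures (`rmse`, `spatial`) the sign of the
#' difference is inverted (lower error on the repeated sequence is better),
#' while for `lag` the raw difference is kept (repeated lag nearer 0,
#' i.e. less negative, is better).
#'
#' @param scores Segment score table as produced by [score_records()]
#'   (columns `subject_id`, `day`, `segment_kind`, `rmse`, `lag_ms`,
#'   `spatial_rmse`).
#' @param day Day to summarize (default: all rows, which then must belong to
#'   one day).
#' @param measures Measures to compute; subset of
#'   `c("rmse", "lag", "spatial")`.
#' @return Data frame with columns `subject_id`, `measure`,
#'   `mean_repeated`, `mean_random`, `diff` and `weight`. Subjects missing a
#'   sequence kind are dropped with a message.
#' @export
difference_scores <- function(scores, day = NULL,
                              measures = c("rmse", "lag", "spatial")) {
  if (!is.null(day)) scores <- scores[scores$day %in% day, , drop = FALSE]
  if (nrow(scores) == 0) stop("no score rows for the requested day", call. = FALSE)
  out <- list()
  for (sid in unique(scores$subject_id)) {
    sub <- scores[scores$subject_id == sid, , drop = FALSE]
    if (!all(c("repeated", "random") %in% sub$segment_kind)) {
      message(sprintf("subject %s: missing a sequence kind, excluded", sid))
      next
    }
    for (m in measures) {
      col <- measure_column(m)
      mr <- mean(sub[[col]][sub$segment_kind == "repeated"], na.rm = TRUE)
      mn <- mean(sub[[col]][sub$segment_kind == "random"], na.rm = TRUE)
      d <- mr - mn
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, measure = m, mean_repeated = mr, mean_random = mn,
        diff = d, weight = if (m == "lag") d else -d,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no subject had both sequence kinds", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count subjects with a positive sequence-specific weight
#'
#' @param x Either a difference-score table from [difference_scores()]
#'   (then `measure` selects the rows) or a numeric vector of weights.
#' @param measure Measure to count when `x` is a table.
#' @return Integer count of strictly positive weights.
#' @export
count_positive <- function(x, measure = NULL) {
  if (is.data.frame(x)) {
    if (is.null(measure))
      stop("`measure` is required when `x` is a table", call. = FALSE)
    x <- x$weight[x$measure == measure]
  }
  sum(x > 0, na.rm = TRUE)
}

#' Bundled retention-test weighted difference scores (reference cohort)
#'
#' Per-participant weighted difference scores (repeated minus random, error
#' signs inverted) at the delayed retention test of a 10-participant
#' continuous-tracking study, for the three performance measures: overall
#' movement error, temporal precision and spatial accuracy. Used as a
#' worked-example input for sign counting and group-image weighting.
#'
#' @return Data frame with columns `participant`, `age`, `sex`,
#'   `overall_error`, `temporal_precision`, `spatial_accuracy`.
#' @export
#' @examples
#' tbl <- weighted_scores_table()
#' count_positive(tbl$temporal_precision)  # 8
weighted_scores_table <- function() {
  path <- system.file("extdata", "retention_weighted_scores.tsv",
                      package = "ctlearn", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Remove group-level outliers
#'
#' Drops values farther than `n_sd` standard deviations from the group mean.
#' Mean and SD are computed once on the full input (no iterative
#' re-screening); the boundary is exclusive, so a value at exactly `n_sd`
#' SDs is retained.
#'
#' @param x Numeric vector, or a data frame with a `column` of change scores.
#' @param column Column name when `x` is a data frame.
#' @param n_sd Threshold in standard deviations (default 2).
#' @return The filtered vector or data frame; removed positions are recorded
#'   in the `removed` attribute.
#' @export
remove_outliers <- function(x, column = NULL, n_sd = 2) {
  v <- if (is.data.frame(x)) {
    if (is.null(column)) stop("`column` is required for a data frame", call. = FALSE)
    x[[column]]
  } else x
  if (length(v) < 3L)
    stop("need at least 3 values to define outliers", call. = FALSE)
  s <- sd(v)
  keep <- if (s == 0) rep(TRUE, length(v)) else abs(v - mean(v)) <= n_sd * s
  out <- if (is.data.frame(x)) x[keep, , drop = FALSE] else x[keep]
  attr(out, "removed") <- which(!keep)
  out
}

#' Day-by-sequence repeated-measures ANOVA
#'
#' Standard two-way within-subject ANOVA (main effects of day and sequence
#' plus their interaction), each effect tested against its own
#' subject-by-effect error stratum, as fitted by [stats::aov()] with an
#' `Error(subject/(day*sequence))` term. Requires a complete balanced design
#' with exactly one value per subject/day/sequence cell.
#'
#' @param data Data frame with columns `subject`, `day`, `sequence`,
#'   `value` (cell means).
#' @return Data frame with one row per effect (`day`, `sequence`,
#'   `day:sequence`): degrees of freedom, sums of squares, `F`, `p` and
#'   partial eta squared. Zero-variance effects report `F = 0, p = 1`;
#'   zero error variance with a non-zero effect reports `F = Inf, p = 0`
#'   and `degenerate = TRUE`. A sphericity (Mauchly) test for the day
#'   factor, when estimable, is attached as attribute `"mauchly"`.
#' @export
rm_anova <- function(data) {
  need <- c("subject", "day", "sequence", "value")
  if (!all(need %in% names(data)))
    stop("`data` must have columns subject, day, sequence, value", call. = FALSE)
  data$subject <- factor(data$subject)
  data$day <- factor(data$day)
  data$sequence <- factor(data$sequence)
  tab <- table(data$subject, data$day, data$sequence)
  if (any(tab != 1L))
    stop("incomplete or unbalanced design: need exactly one value per subject/day/sequence cell",
         call. = FALSE)
  fit <- aov(value ~ day * sequence + Error(subject / (day * sequence)),
             data = data)
  sm <- summary(fit)
  strata <- c(day = "Error: subject:day", sequence = "Error: subject:sequence",
              "day:sequence" = "Error: subject:day:sequence")
  rows <- lapply(names(strata), function(eff) {
    st <- sm[[strata[[eff]]]][[1]]
    rn <- trimws(rownames(st))
    i <- match(eff, rn)
    j <- match("Residuals", rn)
    ss <- st[i, "Sum Sq"]; ss_err <- st[j, "Sum Sq"]
    df1 <- st[i, "Df"]; df2 <- st[j, "Df"]
    eps <- 1e-12 * max(abs(data$value)^2, 1)
    degenerate <- FALSE
    if (ss <= eps) { f <- 0; p <- 1 }
    else if (ss_err <= eps) { f <- Inf; p <- 0; degenerate <- TRUE }
    else { f <- (ss / df1) / (ss_err / df2); p <- pf(f, df1, df2, lower.tail = FALSE) }
    data.frame(effect = eff, df1 = df1, df2 = df2, ss = ss, ss_error = ss_err,
               F = f, p = p,
               partial_eta_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "mauchly") <- mauchly_day(data)
  res
}

# Mauchly sphericity test for the day factor, computed on the
# sequence-averaged subject-by-day matrix via the multivariate fit.
mauchly_day <- function(data) {
  tryCatch({
    ag <- aggregate(value ~ subject + day, data = data, FUN = mean)
    wide <- reshape(ag, direction = "wide", idvar = "subject", timevar = "day")
    Y <- as.matrix(wide[, -1, drop = FALSE])
    if (ncol(Y) < 3L || nrow(Y) <= ncol(Y)) return(NULL)
    mlm <- lm(Y ~ 1)
    idata <- data.frame(day = factor(seq_len(ncol(Y))))
    mt <- mauchly.test(mlm, X = ~ 1, idata = idata)
    list(W = unname(mt$statistic), p = mt$p.value)
  }, error = function(e) NULL)
}

#' Score an explicit-recognition test
#'
#' Forced-choice recognition of 3 true target sequences among 7 foils.
#' Explicit knowledge is credited when at least 2 of the 3 true sequences
#' are recognized and at least 4 of the 7 foils rejected.
#'
#' @param is_true Logical vector of length 10: `TRUE` for the 3 true
#'   sequences, `FALSE` for the 7 foils.
#' @param said_yes Logical vector of length 10: the participant's yes/no
#'   judgments.
#' @return List with `hits`, `correct_rejections`, `percent_correct`
#'   (0-100) and `explicit`.
#' @export
score_recognition <- function(is_true, said_yes) {
  if (length(is_true) != 10L || length(said_yes) != 10L ||
      anyNA(is_true) || anyNA(said_yes))
    stop("expected 10 complete yes/no judgments", call. = FALSE)
  if (sum(is_true) != 3L)
    stop("expected exactly 3 true sequences and 7 foils", call. = FALSE)
  hits <- sum(said_yes & is_true)
  cr <- sum(!said_yes & !is_true)
  list(hits = hits, correct_rejections = cr,
       percent_correct = 100 * (hits + cr) / 10,
       explicit = hits >= 2L && cr >= 4L)
}

#' Normalize practice-day block means for plotting
#'
#' Divides each subject's block means by that subject's first-block mean on
#' the earliest practice day present, separately per measure, giving
#' unit-relative learning curves. Intended for plots only; difference scores
#' always use raw values.
#'
#' @param block_means Data frame with columns `subject_id`, `day`, `block`,
#'   `measure`, `value`.
#' @return The same table with an added `normalized` column.
#' @export
normalize_practice <- function(block_means) {
  need <- c("subject_id", "day", "block", "measure", "value")
  if (!all(need %in% names(block_means)))
    stop("`block_means` must have columns subject_id, day, block, measure, value",
         call. = FALSE)
  out <- block_means
  out$normalized <- NA_real_
  for (sid in unique(out$subject_id)) for (m in unique(out$measure)) {
    idx <- out$subject_id == sid & out$measure == m
    sub <- out[idx, ]
    d0 <- min(sub$day)
    ref <- sub$value[sub$day == d0 & sub$block == min(sub$block[sub$day == d0])][1]
    out$normalized[idx] <- if (!is.na(ref) && ref != 0) sub$value / ref else NA_real_
  }
  out
}
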