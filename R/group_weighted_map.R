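# Behaviorally weighted group statistic image and cluster-extent report.
#
# Each subject's Repeated-Random contrast image is multiplied by that
# subject's behavioral difference-score weight; the weighted images are
# summed and divided by sqrt(N), giving a voxelwise brain-behavior
# correlation statistic. Suprathreshold voxels (one-sided positive tail of
# a standard-normal null) are grouped into connected clusters and clusters
# below the extent threshold are discarded.

#' Behaviorally weighted group image
#'
#' Computes `sum_i w_i * c_i(v) / sqrt(N)` over subjects. Optionally the
#' weights are mean-centred first (removing the confound that an
#' all-positive weight vector makes uniformly activated regions appear
#' behavior-correlated), and/or scaled to unit root-mean-square (so a
#' standard-normal null for the summed statistic is plausible when the
#' per-subject images are unit-scale t images).
#'
#' @param contrasts List of per-subject contrast images: `ct_contrast`
#'   objects or numeric arrays, all with identical dimensions.
#' @param weights Numeric vector, one weight per subject.
#' @param center_weights Mean-centre the weights first (default `FALSE`,
#'   the literal weighting procedure).
#' @param scale_weights `"none"` (default) or `"rms"` (divide by the
#'   root-mean-square weight after any centring).
#' @return Numeric array (same dimensions as the inputs) with attributes
#'   `n` and `weights` (as applied).
#' @export
#' @examples
#' a <- array(c(3, -1), c(1, 1, 2))
#' weight_and_sum(list(a[ , , 1, drop = FALSE] * 0 + 3,
#'                     a[ , , 1, drop = FALSE] * 0 - 1), c(0.5, 1))
weight_and_sum <- function(contrasts, weights, center_weights = FALSE,
                           scale_weights = c("none", "rms")) {
  scale_weights <- match.arg(scale_weights)
  imgs <- lapply(contrasts, function(ci)
    if (inherits(ci, "ct_contrast")) ci$values else ci)
  n <- length(imgs)
  if (n == 0L) stop("no contrast images supplied", call. = FALSE)
  if (length(weights) != n)
    stop("need exactly one weight per contrast image", call. = FALSE)
  check_finite(weights, "weights")
  dims <- dim(imgs[[1]]) %||% length(imgs[[1]])
  for (i in seq_len(n))
    if (!identical(dim(imgs[[i]]) %||% length(imgs[[i]]), dims))
      stop("contrast images must share a common grid", call. = FALSE)
  w <- weights
  if (center_weights) w <- w - mean(w)
  if (scale_weights == "rms") {
    rms <- sqrt(mean(w^2))
    if (rms > 0) w <- w / rms
  }
  acc <- imgs[[1]] * w[1]
  for (i in seq_len(n)[-1]) acc <- acc + imgs[[i]] * w[i]
  out <- acc / sqrt(n)
  attr(out, "n") <- n
  attr(out, "weights") <- w
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1,
                 stop("`connectivity` must be 6, 18 or 26", call. = FALSE))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D mask
#'
#' Flood-fill labeling under face (6), edge (18) or corner (26)
#' connectivity.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 (default), 18 or 26.
#' @return Integer array: 0 outside the mask, component label inside.
#' @export
label_components <- function(mask, connectivity = 6) {
  dims <- dim(mask)
  if (length(dims) != 3L) stop("`mask` must be a 3D array", call. = FALSE)
  off <- neighbor_offsets(connectivity)
  lab <- array(0L, dims)
  nxt <- 0L
  todo <- which(mask)
  for (v in todo) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    lab[v] <- nxt
    frontier <- arrayInd(v, dims)
    while (nrow(frontier)) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                       drop = FALSE] +
        off[rep(seq_len(nrow(off)), nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
        cand[, 2] >= 1 & cand[, 2] <= dims[2] &
        cand[, 3] >= 1 & cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) break
      lin <- cand[, 1] + dims[1] * (cand[, 2] - 1) +
        dims[1] * dims[2] * (cand[, 3] - 1)
      new <- unique(lin[mask[lin] & lab[lin] == 0L])
      if (!length(new)) break
      lab[new] <- nxt
      frontier <- arrayInd(new, dims)
    }
  }
  lab
}

#' Threshold a group image and report clusters
#'
#' Converts the voxelwise statistic to a one-sided p-value under a
#' standard-normal null (positive tail), keeps suprathreshold voxels,
#' labels connected components, and discards clusters smaller than
#' `min_cluster` voxels.
#'
#' @param img Numeric 3D statistic array (e.g. from [weight_and_sum()]).
#' @param p_threshold Voxelwise one-sided p threshold (default 0.005).
#' @param min_cluster Minimum cluster extent in voxels (default 200).
#' @param connectivity Neighborhood definition: 6 (default), 18 or 26.
#' @param voxel_mm Voxel edge length for the mm coordinates in the report
#'   (default 4).
#' @return A `ct_cluster_report`: list with `report` (data frame sorted by
#'   decreasing size: `cluster`, `size_voxels`, `peak_value`,
#'   `peak_x/y/z` 0-based indices, `peak_x/y/z_mm`), `labels` (relabeled
#'   array, 0 = background), `mask` (retained suprathreshold voxels),
#'   `threshold_z`, and the thresholds used.
#' @export
threshold_and_cluster <- function(img, p_threshold = 0.005, min_cluster = 200,
                                  connectivity = 6, voxel_mm = 4) {
  if (anyNA(img) || any(!is.finite(img)))
    stop("`img` must be finite", call. = FALSE)
  z_thr <- qnorm(1 - p_threshold)
  mask <- img > z_thr
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_cluster)
  out_lab <- array(0L, dim(img))
  rows <- list()
  if (length(keep)) {
    ord <- keep[order(sizes[keep], decreasing = TRUE)]
    for (k in seq_along(ord)) {
      vox <- which(lab == ord[k])
      out_lab[vox] <- k
      peak <- vox[which.max(img[vox])]
      pc <- arrayInd(peak, dim(img))
      rows[[k]] <- data.frame(
        cluster = k, size_voxels = sizes[ord[k]],
        peak_value = img[peak],
        peak_x = pc[1] - 1L, peak_y = pc[2] - 1L, peak_z = pc[3] - 1L,
        peak_x_mm = (pc[1] - 1L) * voxel_mm,
        peak_y_mm = (pc[2] - 1L) * voxel_mm,
        peak_z_mm = (pc[3] - 1L) * voxel_mm)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), size_voxels = integer(),
               peak_value = numeric(), peak_x = integer(), peak_y = integer(),
               peak_z = integer(), peak_x_mm = numeric(),
               peak_y_mm = numeric(), peak_z_mm = numeric())
  structure(list(report = report, labels = out_lab, mask = out_lab > 0L,
                 threshold_z = z_thr, p_threshold = p_threshold,
                 min_cluster = min_cluster, connectivity = connectivity),
            class = "ct_cluster_report")
}

#' Separate performance-related from learning-specific activation
#'
#' Activation present on day 1 reflects task performance rather than
#' learning; the learning-specific set is the retention-day (day 7)
#' suprathreshold voxels with the voxels also suprathreshold on day 1
#' removed.
#'
#' @param day1,day7 `ct_cluster_report` objects or logical masks on the
#'   same grid.
#' @return List with logical arrays `overlap` (suprathreshold both days)
#'   and `learning_specific`, plus voxel counts `n_overlap` and
#'   `n_learning_specific`.
#' @export
day_overlap <- function(day1, day7) {
  m1 <- if (inherits(day1, "ct_cluster_report")) day1$mask else day1
  m7 <- if (inherits(day7, "ct_cluster_report")) day7$mask else day7
  if (!identical(dim(m1), dim(m7)))
    stop("day-1 and day-7 masks must share a grid", call. = FALSE)
  overlap <- m1 & m7
  learning <- m7 & !overlap
  list(overlap = overlap, learning_specific = learning,
       n_overlap = sum(overlap), n_learning_specific = sum(learning))
}
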