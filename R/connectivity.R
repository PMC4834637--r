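#' Frame displacement from six motion parameters
#'
#' Sums the absolute frame-to-frame change of all six rigid-body parameters.
#' The three rotational parameters (columns 4-6, radians) are converted to
#' millimetres as arc length on a 50 mm sphere before summation, the
#' convention of the scrubbing literature; set `rotation_radius = NULL` to
#' sum raw radians instead.
#'
#' @param motion Numeric matrix, frames x 6 (translations mm, rotations rad).
#' @param rotation_radius Sphere radius in mm for the rotation-to-arc-length
#'   conversion, or NULL for raw-radian summation.
#' @return Numeric vector of per-frame displacements; the first frame is 0.
#' @export
frame_displacement <- function(motion, rotation_radius = 50) {
  motion <- as.matrix(motion)
  assert_that(ncol(motion) == 6, "`motion` must have exactly 6 columns")
  assert_that(nrow(motion) >= 2, "`motion` needs at least 2 frames")
  scale <- c(rep(1, 3), rep(rotation_radius %||% 1, 3))
  d <- abs(diff(motion)) %*% scale
  c(0, drop(d))
}

#' Mean relative displacement per motion parameter
#'
#' The mean absolute frame-to-frame change of each of the six motion
#' parameters, a per-subject summary used for group motion comparisons.
#'
#' @inheritParams frame_displacement
#' @return Named numeric vector of six values (mm / radians).
#' @export
mean_relative_displacement <- function(motion) {
  motion <- as.matrix(motion)
  assert_that(ncol(motion) == 6, "`motion` must have exactly 6 columns")
  assert_that(nrow(motion) >= 2, "`motion` needs at least 2 frames")
  out <- colMeans(abs(diff(motion)))
  names(out) <- colnames(motion) %||%
    c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  out
}

#' Scrubbing retention mask from a frame-displacement series
#'
#' A frame whose displacement exceeds the threshold is removed together with
#' the previous frame and the two subsequent frames; the retention mask is
#' FALSE at every removed frame.
#'
#' @param fd Nonnegative frame-displacement series.
#' @param threshold Displacement threshold in mm (default 0.5).
#' @return Logical retention mask with attribute `retained_fraction`.
#' @export
scrub_mask <- function(fd, threshold = 0.5) {
  assert_that(all(fd >= 0), "`fd` must be nonnegative")
  n <- length(fd)
  mask <- rep(TRUE, n)
  for (t in which(fd > threshold)) {
    lo <- max(1, t - 1)
    hi <- min(n, t + 2)
    mask[lo:hi] <- FALSE
  }
  attr(mask, "retained_fraction") <- mean(mask)
  mask
}

#' Zero-phase band-pass filter for ROI and nuisance time courses
#'
#' Removes the column means, then applies a second-order Butterworth
#' band-pass forward and backward (zero phase, so temporal correlations are
#' not shifted). The default transmission range is 0.008-0.1 Hz.
#'
#' @param series Numeric vector or frames-x-k matrix.
#' @param tr Seconds per frame (> 0).
#' @param low,high Transmission band edges in Hz; `high` must stay below the
#'   Nyquist frequency 1/(2 tr).
#' @return Filtered series with the input shape.
#' @export
bandpass <- function(series, tr, low = 0.008, high = 0.1) {
  assert_that(tr > 0, "`tr` must be positive")
  nyq <- 1 / (2 * tr)
  assert_that(low > 0 && low < high, "need 0 < low < high")
  assert_that(high < nyq, "`high` must be below the Nyquist frequency")
  flt <- signal::butter(2, c(low, high) / nyq, type = "pass")
  one <- function(x) signal::filtfilt(flt, x - mean(x))
  if (is.matrix(series)) {
    out <- apply(series, 2, one)
    dimnames(out) <- dimnames(series)
    out
  } else {
    one(series)
  }
}

#' Regress nuisance signals out of band-passed ROI series
#'
#' Both the ROI series and the regressors (three tissue signals and six
#' motion parameters) are band-pass filtered first, then each ROI course is
#' linearly regressed on the intercept-augmented regressor block and replaced
#' by its residual. Residuals are orthogonal to every filtered regressor.
#'
#' @param roi_series Frames x regions matrix.
#' @param motion Frames x 6 motion-parameter matrix.
#' @param tissue Frames x 3 tissue-signal matrix (white matter, CSF, whole
#'   brain). The whole-brain (global) column is included as a regressor by
#'   default; drop it beforehand to skip global-signal regression.
#' @inheritParams bandpass
#' @return Frames x regions residual matrix.
#' @export
nuisance_regress <- function(roi_series, motion, tissue, tr,
                             low = 0.008, high = 0.1) {
  roi_series <- as.matrix(roi_series)
  reg <- cbind(as.matrix(tissue), as.matrix(motion))
  assert_that(nrow(reg) == nrow(roi_series),
              "regressors and series must share the frame count")
  yf <- bandpass(roi_series, tr, low, high)
  xf <- cbind(1, bandpass(reg, tr, low, high))
  qx <- qr(xf)
  if (qx$rank < ncol(xf))
    warn("rank-deficient regressor matrix; using pseudo-inverse fit")
  res <- qr.resid(qx, yf)
  dimnames(res) <- dimnames(roi_series)
  res
}

#' Index map of the connectivity vector
#'
#' Position k of the connectivity vector holds the correlation of the region
#' pair (i, j), i > j, in row-major strict-lower-triangle order:
#' (2,1), (3,1), (3,2), (4,1), ... (1-based).
#'
#' @param n_regions Number of regions R.
#' @return Tibble with columns `index`, `region_i`, `region_j`
#'   (`region_i > region_j`), of `R(R-1)/2` rows.
#' @export
fc_index_map <- function(n_regions) {
  i <- rep(2:n_regions, times = 1:(n_regions - 1))
  j <- unlist(lapply(2:n_regions, function(r) seq_len(r - 1)))
  tibble(index = seq_along(i), region_i = i, region_j = j)
}

#' Pearson connectivity vector over retained frames
#'
#' Computes all pairwise Pearson correlations of the (residual) region
#' series over the frames retained by the scrubbing mask, and returns the
#' strict lower triangle in [fc_index_map()] order. A region with zero
#' variance within the mask yields undefined correlations; those entries are
#' stored as 0 with a warning so the vector length stays fixed.
#'
#' @param series Frames x regions matrix (typically nuisance residuals).
#' @param mask Logical retention mask; NULL keeps all frames.
#' @return Numeric vector of length `R(R-1)/2` with attribute `index_map`.
#' @export
fc_vector <- function(series, mask = NULL) {
  series <- as.matrix(series)
  if (is.null(mask)) mask <- rep(TRUE, nrow(series))
  assert_that(length(mask) == nrow(series), "`mask` length must match frames")
  kept <- series[mask, , drop = FALSE]
  assert_that(nrow(kept) >= 5, "need at least 5 retained frames")
  sds <- apply(kept, 2, sd)
  degenerate <- which(sds == 0)
  if (length(degenerate) > 0) {
    warn(paste("zero-variance region(s) within mask:",
               paste(degenerate, collapse = ", "),
               "- their correlations stored as 0"))
    kept[, degenerate] <- kept[, degenerate] +
      matrix(0, nrow(kept), length(degenerate))
  }
  cm <- suppressWarnings(cor(kept))
  cm[!is.finite(cm)] <- 0
  im <- fc_index_map(ncol(series))
  values <- cm[cbind(im$region_i, im$region_j)]
  attr(values, "index_map") <- im
  values
}

#' Full single-subject connectivity pipeline
#'
#' Fixed processing order: band-pass filtering of the full series, nuisance
#' regression against filtered tissue and motion regressors, then Pearson
#' correlation restricted to the frames surviving motion scrubbing. Filtering
#' always sees the complete series; frame exclusion happens only at the
#' correlation stage.
#'
#' @inheritParams nuisance_regress
#' @param fd_threshold Scrubbing threshold in mm.
#' @param rotation_radius Passed to [frame_displacement()].
#' @return A list with `fc` (connectivity vector) and `qc` (one-row tibble:
#'   mean and max frame displacement, retained fraction, frame counts).
#' @export
fc_pipeline <- function(roi_series, motion, tissue, tr, fd_threshold = 0.5,
                        low = 0.008, high = 0.1, rotation_radius = 50) {
  assert_that(nrow(as.matrix(roi_series)) >= 12,
              "need at least 12 frames for filtering")
  fd <- frame_displacement(motion, rotation_radius)
  mask <- scrub_mask(fd, fd_threshold)
  residuals <- nuisance_regress(roi_series, motion, tissue, tr, low, high)
  fc <- fc_vector(residuals, mask)
  qc <- tibble(
    n_frames = length(fd),
    n_retained = sum(mask),
    retained_fraction = attr(mask, "retained_fraction"),
    mean_fd = mean(fd),
    max_fd = max(fd))
  list(fc = fc, qc = qc)
}
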