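#' Costes automatic threshold for a channel pair
#'
#' Selects the threshold pair below which the two channels show no positive
#' correlation. A least-squares regression `ch2 = a * ch1 + b` is fitted
#' over the masked pixels; candidate thresholds `T1` descend through the
#' sorted unique intensities of channel 1 with `T2 = a * T1 + b`, and the
#' scan stops at the highest `T1` for which the Pearson correlation of the
#' pixels with `ch1 < T1` and `ch2 < T2` is <= 0. If the below-threshold
#' correlation never becomes non-positive the channel minima are returned
#' (every pixel counts as signal).
#'
#' @param ch1,ch2 numeric matrices of identical dimension.
#' @param mask logical matrix (same dim) selecting the analysed pixels;
#'   `NULL` analyses everything.
#' @return list: `threshold_1`, `threshold_2`, `slope`, `intercept`.
#' @export
costes_auto_threshold <- function(ch1, ch2, mask = NULL) {
  check_pair(ch1, ch2, mask)
  if (is.null(mask)) mask <- array(TRUE, dim(ch1))
  v1 <- ch1[mask]; v2 <- ch2[mask]
  if (length(v1) < 2) stop("mask selects fewer than 2 pixels")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance channel inside the mask: regression undefined")
  a <- stats::cov(v1, v2) / stats::var(v1)
  b <- mean(v2) - a * mean(v1)

  cand <- sort(unique(v1), decreasing = TRUE)
  t1 <- min(v1); t2 <- min(v2)          # fallback: floor
  for (T1 in cand) {
    T2 <- a * T1 + b
    below <- v1 < T1 & v2 < T2
    if (sum(below) < 2) next
    b1 <- v1[below]; b2 <- v2[below]
    if (stats::sd(b1) == 0 || stats::sd(b2) == 0) next
    r <- stats::cor(b1, b2)
    if (is.finite(r) && r <= 0) { t1 <- T1; t2 <- T2; break }
  }
  list(threshold_1 = t1, threshold_2 = t2, slope = a, intercept = b)
}

#' Thresholded Mander's overlap coefficients
#'
#' `tM1` is the fraction of channel-1 intensity, summed over pixels above
#' its threshold, that falls where channel 2 is also above its threshold;
#' `tM2` is the symmetric quantity for channel 2. With
#' `denominator = "all"` the denominator sums the whole (masked) channel
#' instead of only its above-threshold pixels.
#'
#' @param ch1,ch2 numeric matrices of identical dimension.
#' @param threshold_1,threshold_2 intensity thresholds (exclusive: pixels
#'   count when strictly above).
#' @param mask optional logical matrix restricting the analysis.
#' @param denominator `"thresholded"` (default) or `"all"`.
#' @return list: `tM1`, `tM2`, and `undefined` — TRUE when a channel has no
#'   above-threshold pixels (its coefficient is NA, never silently 0).
#' @export
manders_thresholded <- function(ch1, ch2, threshold_1, threshold_2,
                                mask = NULL,
                                denominator = c("thresholded", "all")) {
  check_pair(ch1, ch2, mask)
  denominator <- match.arg(denominator)
  stopifnot(is.finite(threshold_1), is.finite(threshold_2))
  if (is.null(mask)) mask <- array(TRUE, dim(ch1))
  v1 <- ch1[mask]; v2 <- ch2[mask]
  a1 <- v1 > threshold_1
  a2 <- v2 > threshold_2
  den1 <- if (denominator == "thresholded") sum(v1[a1]) else sum(v1)
  den2 <- if (denominator == "thresholded") sum(v2[a2]) else sum(v2)
  tM1 <- if (any(a1) && den1 > 0) sum(v1[a1 & a2]) / den1 else NA_real_
  tM2 <- if (any(a2) && den2 > 0) sum(v2[a1 & a2]) / den2 else NA_real_
  list(tM1 = tM1, tM2 = tM2, undefined = !any(a1) || !any(a2))
}

#' Rotation null for random colocalization
#'
#' Rotates channel 2 by 90 degrees counterclockwise about the center of the
#' analysed region and re-runs the full threshold + Mander's measurement on
#' the rotated pair. True colocalization is destroyed by the rotation while
#' the intensity statistics of both channels are preserved, so the rotated
#' coefficients estimate the chance-overlap floor.
#'
#' @param ch1,ch2 numeric matrices.
#' @param mask optional logical matrix; its bounding box defines the
#'   rotated region.
#' @param pad allow padding a non-square region to a square (with the
#'   region's median intensity) before rotating? If `FALSE`, a non-square
#'   region is an error.
#' @param denominator passed to [manders_thresholded()].
#' @return list: `null_tM1`, `null_tM2`, `threshold_1`, `threshold_2`.
#' @export
rotation_null <- function(ch1, ch2, mask = NULL, pad = TRUE,
                          denominator = c("thresholded", "all")) {
  check_pair(ch1, ch2, mask)
  denominator <- match.arg(denominator)
  if (is.null(mask)) mask <- array(TRUE, dim(ch1))
  bb <- mask_bbox(mask)
  sub2 <- ch2[bb$ys, bb$xs, drop = FALSE]
  if (nrow(sub2) != ncol(sub2)) {
    if (!pad)
      stop("non-square region: rotation needs pad = TRUE or a square ROI")
    n <- max(dim(sub2))
    padded <- matrix(stats::median(sub2), n, n)
    oy <- floor((n - nrow(sub2)) / 2); ox <- floor((n - ncol(sub2)) / 2)
    padded[oy + seq_len(nrow(sub2)), ox + seq_len(ncol(sub2))] <- sub2
    rot <- rot90_ccw(padded)
    sub2 <- rot[oy + seq_len(nrow(sub2)), ox + seq_len(ncol(sub2)),
                drop = FALSE]
  } else {
    sub2 <- rot90_ccw(sub2)
  }
  ch2r <- ch2
  ch2r[bb$ys, bb$xs] <- sub2
  thr <- costes_auto_threshold(ch1, ch2r, mask)
  m <- manders_thresholded(ch1, ch2r, thr$threshold_1, thr$threshold_2,
                           mask, denominator)
  list(null_tM1 = m$tM1, null_tM2 = m$tM2,
       threshold_1 = thr$threshold_1, threshold_2 = thr$threshold_2)
}

# 90 degrees counterclockwise, rows = y (top first), cols = x
rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  list(ys = min(idx[, 1]):max(idx[, 1]), xs = min(idx[, 2]):max(idx[, 2]))
}

check_pair <- function(ch1, ch2, mask = NULL) {
  stopifnot(is.numeric(ch1), is.numeric(ch2), is.matrix(ch1), is.matrix(ch2))
  if (!all(dim(ch1) == dim(ch2)))
    stop("channel images must have identical dimensions")
  if (!is.null(mask)) {
    stopifnot(is.logical(mask))
    if (!all(dim(mask) == dim(ch1)))
      stop("mask must match the channel dimensions")
    if (!any(mask)) stop("empty mask")
  }
}

#' Per-cell colocalization pipeline
#'
#' For each cell mask: Costes thresholds, thresholded Mander's tM1/tM2 and
#' the 90-degree rotation null, on one channel pair of an image stack.
#'
#' @param stack an [image_stack()] (first frame/slice is analysed).
#' @param ch_a,ch_b channel indices or names; `tM1` is the fraction of
#'   `ch_a` signal colocalizing with `ch_b`.
#' @param cell_masks list of logical matrices (one per cell), or a single
#'   matrix for one cell; `NULL` analyses the full frame as one cell.
#' @param rotate_null compute the rotation-null coefficients?
#' @param denominator passed to [manders_thresholded()].
#' @return data.frame: cell_id, tM1, tM2, T1, T2, null_tM1, null_tM2.
#' @export
coloc_pipeline <- function(stack, ch_a = 1, ch_b = 2, cell_masks = NULL,
                           rotate_null = TRUE,
                           denominator = c("thresholded", "all")) {
  stopifnot(inherits(stack, "image_stack"))
  denominator <- match.arg(denominator)
  ch1 <- stack_plane(stack, c = ch_a)
  ch2 <- stack_plane(stack, c = ch_b)
  if (is.null(cell_masks)) cell_masks <- list(array(TRUE, dim(ch1)))
  if (is.matrix(cell_masks)) cell_masks <- list(cell_masks)
  rows <- lapply(seq_along(cell_masks), function(i) {
    mask <- cell_masks[[i]]
    if (!all(dim(mask) == dim(ch1)))
      stop("cell mask ", i, " does not match the image bounds")
    thr <- costes_auto_threshold(ch1, ch2, mask)
    m <- manders_thresholded(ch1, ch2, thr$threshold_1, thr$threshold_2,
                             mask, denominator)
    nl <- if (rotate_null)
      rotation_null(ch1, ch2, mask, denominator = denominator)
    else list(null_tM1 = NA_real_, null_tM2 = NA_real_)
    data.frame(cell_id = i, tM1 = m$tM1, tM2 = m$tM2,
               T1 = thr$threshold_1, T2 = thr$threshold_2,
               null_tM1 = nl$null_tM1, null_tM2 = nl$null_tM2)
  })
  do.call(rbind, rows)
}

#' Disc mask for a simulated cell
#'
#' Convenience ROI builder from simulator geometry: TRUE inside the cell
#' disc (optionally grown by `margin_px` pixels).
#'
#' @param geometry a [cell_geometry()].
#' @param grid an [acquisition_grid()].
#' @param margin_px extra radius, pixels.
#' @return logical matrix (y, x).
#' @export
cell_disc_mask <- function(geometry, grid, margin_px = 2) {
  center <- grid_center(geometry, grid)
  ny <- grid$shape[["y"]]; nx <- grid$shape[["x"]]
  r_px <- geometry$cell_radius_nm / grid$pixel_size_nm + margin_px
  d2 <- outer((0:(ny - 1) - center[1])^2, (0:(nx - 1) - center[2])^2, "+")
  d2 <= r_px^2
}
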