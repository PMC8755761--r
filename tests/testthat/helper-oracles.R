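# Independent reference implementations and fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# Exhaustive Costes scan: evaluate the below-threshold correlation at EVERY
# observed ch1 intensity, collect all candidates with r <= 0, return the
# highest. Regression via stats::lm.
oracle_costes <- function(ch1, ch2, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(ch1))
  v1 <- ch1[mask]; v2 <- ch2[mask]
  cf <- stats::coef(stats::lm(v2 ~ v1))
  a <- unname(cf[2]); b <- unname(cf[1])
  hits <- c()
  for (T1 in unique(v1)) {
    T2 <- a * T1 + b
    sel <- v1 < T1 & v2 < T2
    if (sum(sel) < 2) next
    if (stats::sd(v1[sel]) == 0 || stats::sd(v2[sel]) == 0) next
    r <- suppressWarnings(stats::cor(v1[sel], v2[sel]))
    if (is.finite(r) && r <= 0) hits <- c(hits, T1)
  }
  if (length(hits)) {
    T1 <- max(hits)
    list(threshold_1 = T1, threshold_2 = a * T1 + b, slope = a, intercept = b)
  } else {
    list(threshold_1 = min(v1), threshold_2 = min(v2),
         slope = a, intercept = b)
  }
}

# Mander's coefficients by explicit per-pixel loops
oracle_manders <- function(ch1, ch2, T1, T2, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(ch1))
  num1 <- den1 <- num2 <- den2 <- 0
  for (i in seq_len(nrow(ch1))) for (j in seq_len(ncol(ch1))) {
    if (!mask[i, j]) next
    a1 <- ch1[i, j] > T1
    a2 <- ch2[i, j] > T2
    if (a1) {
      den1 <- den1 + ch1[i, j]
      if (a2) num1 <- num1 + ch1[i, j]
    }
    if (a2) {
      den2 <- den2 + ch2[i, j]
      if (a1) num2 <- num2 + ch2[i, j]
    }
  }
  list(tM1 = if (den1 > 0) num1 / den1 else NA_real_,
       tM2 = if (den2 > 0) num2 / den2 else NA_real_)
}

# Render a field of Gaussian spots directly (independent of the package
# renderer): amplitude-parameterized, not flux-normalized.
oracle_spot_field <- function(ny, nx, centers, amplitude, sigma_px,
                              baseline = 0) {
  img <- matrix(baseline, ny, nx)
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  for (k in seq_len(nrow(centers)))
    img <- img + amplitude *
      exp(-((yy - centers[k, 1])^2 + (xx - centers[k, 2])^2) /
            (2 * sigma_px^2))
  img
}

# Fraction of frame-to-frame links that connect the same true particle.
# Linked spots are matched back to the truth table by exact coordinates.
link_accuracy <- function(linked, truth) {
  key <- paste(round(truth$y_px, 6), round(truth$x_px, 6), truth$frame)
  vid <- truth$vesicle_id[
    match(paste(round(linked$y_px, 6), round(linked$x_px, 6), linked$frame),
          key)]
  ok <- 0L; tot <- 0L
  for (tid in unique(linked$track_id)) {
    v <- vid[linked$track_id == tid]
    if (length(v) < 2) next
    ok <- ok + sum(v[-1] == v[-length(v)])
    tot <- tot + length(v) - 1L
  }
  list(correct = ok, total = tot,
       fraction = if (tot > 0) ok / tot else NA_real_)
}

# Sparse wide-field Brownian scene for linker validation: many resolvable
# tracks rather than the crowded default B-cell annulus.
tracking_scene <- function(seed, n_vesicles = 50, D = 1e4, n_frames = 50,
                           dt = 5) {
  geom <- shipquant::cell_geometry(cell_radius_nm = 16000,
                                   nucleus_radius_nm = 3000)
  grid <- shipquant::acquisition_grid(
    pixel_size_nm = 80, shape = c(t = n_frames, z = 1, y = 440, x = 440),
    channel_names = "antigen", frame_interval_s = dt)
  shipquant::simulate_timelapse(geom, grid, n_vesicles = n_vesicles,
                                D_nm2_s = D, noise = FALSE, seed = seed)
}
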