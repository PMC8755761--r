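#' Link detected spots across frames into tracks
#'
#' Greedy mutual-nearest-neighbour linking: for each consecutive frame
#' pair, a spot in frame `t` links to a spot in frame `t+1` only if each is
#' the other's nearest neighbour and their distance is below
#' `max_disp_nm`. Unmatched spots start new tracks; there is no gap
#' closing, splitting or merging — a missed detection ends a track. The
#' assignment is independent of the order in which spots are listed within
#' a frame.
#'
#' @param frames list of per-frame spot tables (data.frames with y_px,
#'   x_px; empty frames allowed), or a single `spot_list` with a `frame`
#'   column.
#' @param max_disp_nm displacement gate, nm (> 0).
#' @param pixel_size_nm nm per pixel for the spot coordinates.
#' @return data.frame of class `track_list`: track_id, frame, y_px, x_px,
#'   y_nm, x_nm (one row per spot, frames strictly increasing per track).
#' @export
link_spots <- function(frames, max_disp_nm, pixel_size_nm) {
  stopifnot(max_disp_nm > 0, pixel_size_nm > 0)
  if (is.data.frame(frames)) {
    stopifnot("frame" %in% names(frames))
    fr_ids <- sort(unique(frames$frame))
    frames <- lapply(fr_ids, function(f) frames[frames$frame == f, ])
  }
  n_frames <- length(frames)
  gate_px <- max_disp_nm / pixel_size_nm
  next_track <- 0L
  rows <- list()
  prev_tracks <- integer()       # track id of each spot in previous frame
  prev_pos <- NULL
  for (fr in seq_len(n_frames)) {
    sp <- frames[[fr]]
    n <- if (is.null(sp)) 0L else nrow(sp)
    cur_tracks <- integer(n)
    if (n > 0) {
      pos <- cbind(sp$y_px, sp$x_px)
      if (!is.null(prev_pos) && nrow(prev_pos) > 0) {
        d <- outer(prev_pos[, 1], pos[, 1], "-")^2 +
             outer(prev_pos[, 2], pos[, 2], "-")^2
        d <- sqrt(d)
        nn_fwd <- apply(d, 1, which.min)   # prev -> cur
        nn_bwd <- apply(d, 2, which.min)   # cur -> prev
        for (i in seq_len(nrow(prev_pos))) {
          j <- nn_fwd[i]
          if (nn_bwd[j] == i && d[i, j] <= gate_px)
            cur_tracks[j] <- prev_tracks[i]
        }
      }
      for (j in seq_len(n)) {
        if (cur_tracks[j] == 0L) {
          next_track <- next_track + 1L
          cur_tracks[j] <- next_track
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = cur_tracks, frame = fr,
        y_px = sp$y_px, x_px = sp$x_px,
        y_nm = sp$y_px * pixel_size_nm, x_nm = sp$x_px * pixel_size_nm)
      prev_pos <- pos
    } else {
      prev_pos <- NULL
    }
    prev_tracks <- cur_tracks
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(track_id = integer(), frame = integer(),
                         y_px = numeric(), x_px = numeric(),
                         y_nm = numeric(), x_nm = numeric())
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("track_list", "data.frame")
  out
}

# time-averaged MSD of one track at integer lags (nm^2)
track_msd <- function(y_nm, x_nm, lags) {
  vapply(lags, function(L) {
    n <- length(y_nm) - L
    if (n < 1) return(NA_real_)
    mean((y_nm[(1 + L):(n + L)] - y_nm[1:n])^2 +
         (x_nm[(1 + L):(n + L)] - x_nm[1:n])^2)
  }, numeric(1))
}

#' Per-track and ensemble motility statistics
#'
#' For each track of length >= `min_length`: track length, net
#' displacement, the time-averaged MSD at the first `n_lags` lags, and the
#' apparent 2-D diffusion coefficient `D = slope(MSD vs lag time) / 4`
#' from a linear fit. Directed (drift-dominated) motion makes the MSD
#' quadratic in lag; each track carries a curvature flag when a quadratic
#' term improves the MSD fit substantially, signalling that the linear
#' `D` is not interpretable.
#'
#' @param tracks a `track_list` from [link_spots()], or a data.frame with
#'   track_id, frame, y_nm, x_nm.
#' @param frame_interval_s seconds between frames.
#' @param n_lags MSD lags used for the fit.
#' @param min_length minimum track length (frames) for a D estimate.
#' @return list: `per_track` (track_id, n_frames, displacement_nm,
#'   D_nm2_s, curved), `D_mean`, `D_se`, `n_excluded` (too-short tracks),
#'   `msd` (lag_s, msd_nm2 ensemble means).
#' @export
track_stats <- function(tracks, frame_interval_s, n_lags = 4,
                        min_length = 3) {
  stopifnot(all(c("track_id", "frame", "y_nm", "x_nm") %in% names(tracks)),
            frame_interval_s > 0)
  split_tracks <- split(tracks, tracks$track_id)
  lags <- seq_len(n_lags)
  per <- list()
  n_excluded <- 0L
  msd_acc <- matrix(NA_real_, length(split_tracks), n_lags)
  for (k in seq_along(split_tracks)) {
    tr <- split_tracks[[k]]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < min_length) { n_excluded <- n_excluded + 1L; next }
    msd <- track_msd(tr$y_nm, tr$x_nm, lags)
    msd_acc[k, ] <- msd
    usable <- is.finite(msd)
    tau <- lags[usable] * frame_interval_s
    mm <- msd[usable]
    if (length(mm) >= 2) {
      fit <- stats::lm(mm ~ tau)
      D <- unname(stats::coef(fit)[2]) / 4
      curved <- FALSE
      if (length(mm) >= 3) {
        fit2 <- stats::lm(mm ~ tau + I(tau^2))
        # quadratic term dominating the linear one over the fitted lags
        c2 <- stats::coef(fit2)
        curved <- is.finite(c2[3]) &&
          abs(c2[3]) * max(tau) > 0.5 * abs(c2[2])
      }
    } else { D <- NA_real_; curved <- NA }
    per[[length(per) + 1L]] <- data.frame(
      track_id = tr$track_id[1], n_frames = nrow(tr),
      displacement_nm = sqrt((tr$y_nm[nrow(tr)] - tr$y_nm[1])^2 +
                             (tr$x_nm[nrow(tr)] - tr$x_nm[1])^2),
      D_nm2_s = D, curved = curved)
  }
  per_track <- if (length(per)) do.call(rbind, per)
    else data.frame(track_id = integer(), n_frames = integer(),
                    displacement_nm = numeric(), D_nm2_s = numeric(),
                    curved = logical())
  Ds <- per_track$D_nm2_s[is.finite(per_track$D_nm2_s)]
  list(per_track = per_track,
       D_mean = if (length(Ds)) mean(Ds) else NA_real_,
       D_se = if (length(Ds) > 1) stats::sd(Ds) / sqrt(length(Ds))
              else NA_real_,
       n_excluded = n_excluded,
       msd = data.frame(lag_s = lags * frame_interval_s,
                        msd_nm2 = colMeans(msd_acc, na.rm = TRUE)))
}
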