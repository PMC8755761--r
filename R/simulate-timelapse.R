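#' Simulate a live-imaging timelapse with mid-acquisition quenching
#'
#' Single-channel movie of one cell: vesicles perform 2-D Brownian motion
#' (per-axis step variance `2 * D * dt`) with optional constant drift,
#' reflected at the cytoplasmic annulus boundaries; the membrane ring is
#' multiplied by `1 - q * (1 - exp(-(t - t_q) / tau_q))` from the quench
#' frame onwards, reproducing the seconds-scale collapse of the surface
#' signal after quencher addition while vesicle spots are untouched.
#' Ground-truth tracks (nm and pixel coordinates per frame) are returned
#' with the movie.
#'
#' @param geometry a [cell_geometry()].
#' @param grid an [acquisition_grid()]; `shape["t"]` is the frame count.
#' @param kinetics a [kinetics_model()]; sets pool sizes at `t0_min`.
#' @param quench a [quench_model()].
#' @param t0_min activation time at the first frame, minutes.
#' @param n_vesicles number of moving vesicles.
#' @param D_nm2_s diffusion coefficient, nm^2/s (>= 0).
#' @param drift_nm_s constant drift `(vy, vx)`, nm/s.
#' @param quench_frame 1-based frame at which QP is added, or `NULL` for no
#'   quenching during the movie.
#' @param vesicle_fwhm_nm physical vesicle size (Gaussian FWHM), nm.
#' @param photons_total antigen photon budget per frame before quench/decay.
#' @param noise,offset,read_sd as in [simulate_cell_image()].
#' @param seed integer RNG seed.
#' @return list with `stack` (frames x 1 x 1 x y x x [image_stack()]) and
#'   `truth` (tracks data.frame: frame, vesicle_id, y_nm, x_nm, y_px, x_px;
#'   plus quench_frame and motion parameters).
#' @export
simulate_timelapse <- function(geometry = cell_geometry(),
                               grid = acquisition_grid(
                                 shape = c(t = 50, z = 1, y = 192, x = 192),
                                 channel_names = "antigen"),
                               kinetics = kinetics_model(),
                               quench = quench_model(),
                               t0_min = 20,
                               n_vesicles = 15,
                               D_nm2_s = 1e4,
                               drift_nm_s = c(0, 0),
                               quench_frame = NULL,
                               vesicle_fwhm_nm = 150,
                               photons_total = 2e5,
                               noise = TRUE,
                               offset = 100,
                               read_sd = 2,
                               seed = 1) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(grid, "acquisition_grid"),
            n_vesicles >= 0, length(drift_nm_s) == 2)
  if (D_nm2_s < 0) stop("diffusion coefficient D must be >= 0")
  n_frames <- grid$shape[["t"]]
  dt <- grid$frame_interval_s
  if (!is.null(quench_frame) &&
      (quench_frame < 1 || quench_frame > n_frames))
    stop("quench_frame outside the time axis")
  rng <- local_rng(seed)
  center <- grid_center(geometry, grid)
  check_cell_fits(geometry, grid, center)
  px <- grid$pixel_size_nm
  ny <- grid$shape[["y"]]; nx <- grid$shape[["x"]]

  r_in <- geometry$nucleus_radius_nm
  r_out <- geometry$cell_radius_nm - geometry$membrane_thickness_nm
  sigma_spot_px <- sqrt(fwhm_to_sigma(vesicle_fwhm_nm)^2 +
                        fwhm_to_sigma(grid$psf_fwhm_nm[1])^2) / px
  sigma_mem_px <- sqrt(fwhm_to_sigma(geometry$membrane_thickness_nm)^2 +
                       fwhm_to_sigma(grid$psf_fwhm_nm[1])^2) / px

  # Brownian + drift positions, radially reflected into (r_in, r_out)
  pos <- sample_annulus(n_vesicles, r_in, r_out)
  step_sd <- sqrt(2 * D_nm2_s * dt)
  tracks <- vector("list", n_frames)
  positions <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    if (fr > 1 && n_vesicles > 0) {
      pos <- pos + matrix(stats::rnorm(2 * n_vesicles, sd = step_sd),
                          ncol = 2) +
        rep(drift_nm_s * dt, each = n_vesicles)
      r <- pmax(sqrt(rowSums(pos^2)), 1e-9)
      # exact multi-bounce radial reflection: fold r into [r_in, r_out]
      # with a triangle wave of period 2 * (r_out - r_in)
      w <- r_out - r_in
      x <- (r - r_in) %% (2 * w)
      r_new <- r_in + ifelse(x > w, 2 * w - x, x)
      pos <- pos * (r_new / r)
    }
    positions[[fr]] <- pos
    if (n_vesicles > 0)
      tracks[[fr]] <- data.frame(
        frame = fr, vesicle_id = seq_len(n_vesicles),
        y_nm = pos[, 1], x_nm = pos[, 2],
        y_px = center[1] + pos[, 1] / px,
        x_px = center[2] + pos[, 2] / px)
  }

  f <- internalized_fraction(kinetics, t0_min)
  decay <- exp(-kinetics$decay_delta * t0_min)
  vesicle_photons <- if (n_vesicles > 0)
    photons_total * f * decay / n_vesicles else 0

  data <- array(0, dim = c(n_frames, 1, 1, ny, nx))
  ring <- render_ring(ny, nx, center,
                      (geometry$cell_radius_nm -
                       geometry$membrane_thickness_nm / 2) / px,
                      sigma_mem_px, photons_total * (1 - f))
  for (fr in seq_len(n_frames)) {
    s_after <- if (is.null(quench_frame)) -1 else (fr - quench_frame) * dt
    img <- ring * quench_factor(quench, s_after)
    p <- positions[[fr]]
    if (n_vesicles > 0)
      for (i in seq_len(n_vesicles))
        img <- add_spot(img, center[1] + p[i, 1] / px,
                        center[2] + p[i, 2] / px,
                        sigma_spot_px, vesicle_photons)
    data[fr, 1, 1, , ] <- if (noise) apply_noise(img, offset, read_sd)
                          else img + offset
  }

  stack <- image_stack(data, px, grid$channel_names[1],
                       grid$frame_interval_s, grid$psf_fwhm_nm[1])
  truth <- simulation_truth(
    kind = "timelapse",
    vesicles = NULL,
    params = list(geometry = unclass(geometry), grid = unclass(grid),
                  kinetics = unclass(kinetics), quench = unclass(quench),
                  t0_min = t0_min, n_vesicles = n_vesicles,
                  D_nm2_s = D_nm2_s, drift_nm_s = drift_nm_s,
                  vesicle_fwhm_nm = vesicle_fwhm_nm,
                  photons_total = photons_total, noise = noise,
                  offset = offset, read_sd = read_sd),
    seed = seed,
    center_px = center,
    quench_frame = quench_frame,
    tracks = if (n_vesicles > 0) do.call(rbind, tracks) else NULL)
  list(stack = stack, truth = truth)
}
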