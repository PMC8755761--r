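# Scene rendering ------------------------------------------------------------
# Every structure is an isotropic Gaussian; the rendered spot sigma is the
# quadrature sum of the structure sigma and the channel PSF sigma, which
# keeps the apparent-size arithmetic (FWHM_app^2 = FWHM_struct^2 +
# FWHM_psf^2) exact and testable in closed form. Kernels are normalized
# over their in-image support so the noise-free image integral equals the
# configured photon budget by construction.

# add `photons` worth of a Gaussian spot at 0-based pixel-center (y, x)
add_spot <- function(img, y, x, sigma_px, photons) {
  ny <- nrow(img); nx <- ncol(img)
  h <- ceiling(5 * sigma_px)
  ys <- max(0, floor(y - h)):min(ny - 1, ceiling(y + h))
  xs <- max(0, floor(x - h)):min(nx - 1, ceiling(x + h))
  if (!length(ys) || !length(xs)) return(img)
  ky <- exp(-(ys - y)^2 / (2 * sigma_px^2))
  kx <- exp(-(xs - x)^2 / (2 * sigma_px^2))
  k <- outer(ky, kx)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + photons * k / sum(k)
  img
}

# membrane shell: ring at radius r_px with radial Gaussian cross-section
render_ring <- function(ny, nx, center_yx, r_px, sigma_px, photons) {
  d <- sqrt(outer((0:(ny - 1) - center_yx[1])^2,
                  (0:(nx - 1) - center_yx[2])^2, "+"))
  w <- exp(-(d - r_px)^2 / (2 * sigma_px^2))
  photons * w / sum(w)
}

# area-uniform positions in the cytoplasmic annulus, nm from cell center
sample_annulus <- function(n, r_inner_nm, r_outer_nm) {
  r <- sqrt(stats::runif(n, r_inner_nm^2, r_outer_nm^2))
  theta <- stats::runif(n, 0, 2 * pi)
  cbind(y_nm = r * sin(theta), x_nm = r * cos(theta))
}

apply_noise <- function(img, offset, read_sd) {
  noisy <- matrix(stats::rpois(length(img), lambda = pmax(img, 0)),
                  nrow(img), ncol(img))
  noisy + offset + matrix(stats::rnorm(length(img), sd = read_sd),
                          nrow(img), ncol(img))
}

grid_center <- function(geometry, grid) {
  if (!is.null(geometry$center_px)) geometry$center_px
  else (unname(grid$shape[c("y", "x")]) - 1) / 2
}

check_cell_fits <- function(geometry, grid, center) {
  r_px <- geometry$cell_radius_nm / grid$pixel_size_nm
  ny <- grid$shape[["y"]]; nx <- grid$shape[["x"]]
  if (center[1] - r_px < 0 || center[1] + r_px > ny - 1 ||
      center[2] - r_px < 0 || center[2] + r_px > nx - 1)
    stop("cell geometry does not fit inside the acquisition grid")
}

#' Simulate a two-channel image of one cell in the quench assay
#'
#' Renders a fixed-timepoint snapshot of the assay: channel 1 (antigen)
#' carries a membrane ring proportional to the surface fraction
#' `1 - f(t)` — attenuated by `1 - efficiency_q` when `quenched = TRUE` —
#' plus diffraction-limited vesicle spots proportional to the internalized,
#' decay-attenuated fraction; channel 2 (vesicle marker) carries spots at a
#' `coloc_fraction` subset of the vesicle positions plus `n_marker_extra`
#' independently placed marker spots. Optionally Poisson shot noise,
#' Gaussian read noise and a constant camera offset are applied.
#'
#' @param geometry a [cell_geometry()].
#' @param grid an [acquisition_grid()] (t and z extents must be 1 here).
#' @param kinetics a [kinetics_model()].
#' @param quench a [quench_model()].
#' @param t_min activation time, minutes.
#' @param quenched logical: was the quenching probe added?
#' @param n_vesicles number of internalized vesicles (>= 0).
#' @param coloc_fraction fraction of vesicles carrying the channel-2 marker,
#'   in \[0, 1\].
#' @param n_marker_extra independent marker-only spots; default fills the
#'   marker channel up to `n_vesicles` spots.
#' @param vesicle_fwhm_nm physical vesicle size (Gaussian FWHM), nm.
#' @param photons_total antigen photon budget of the cell before quenching
#'   and decay (surface + internal pools).
#' @param brightness_sdlog per-vesicle log-normal brightness spread.
#' @param noise apply Poisson + read noise? Noise-free images satisfy exact
#'   flux conservation.
#' @param offset constant camera offset (a.u.).
#' @param read_sd Gaussian read-noise sd (a.u.).
#' @param seed integer RNG seed.
#' @return list with `stack` (an [image_stack()]) and `truth` (a
#'   `simulation_truth` with per-vesicle positions, photons and marker
#'   flags, and the rendered pool budgets).
#' @examples
#' sim <- simulate_cell_image(n_vesicles = 10, seed = 1)
#' sim$stack
#' head(sim$truth$vesicles)
#' @export
simulate_cell_image <- function(geometry = cell_geometry(),
                                grid = acquisition_grid(),
                                kinetics = kinetics_model(),
                                quench = quench_model(),
                                t_min = 10,
                                quenched = TRUE,
                                n_vesicles = 25,
                                coloc_fraction = 0.45,
                                n_marker_extra = NULL,
                                vesicle_fwhm_nm = 150,
                                photons_total = 2e5,
                                brightness_sdlog = 0.3,
                                noise = TRUE,
                                offset = 100,
                                read_sd = 2,
                                seed = 1) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(grid, "acquisition_grid"),
            n_vesicles >= 0, coloc_fraction >= 0, coloc_fraction <= 1,
            length(grid$channel_names) >= 2)
  rng <- local_rng(seed)
  center <- grid_center(geometry, grid)
  check_cell_fits(geometry, grid, center)
  px <- grid$pixel_size_nm
  ny <- grid$shape[["y"]]; nx <- grid$shape[["x"]]

  f <- internalized_fraction(kinetics, t_min)
  decay <- exp(-kinetics$decay_delta * t_min)
  membrane_photons <- photons_total * (1 - f) *
    (if (quenched) 1 - quench$efficiency_q else 1)
  vesicle_photons_total <- photons_total * f * decay

  sigma_struct <- fwhm_to_sigma(vesicle_fwhm_nm)
  sigma_spot_px <- sqrt(sigma_struct^2 +
                        fwhm_to_sigma(grid$psf_fwhm_nm)^2) / px
  sigma_mem_px <- sqrt(fwhm_to_sigma(geometry$membrane_thickness_nm)^2 +
                       fwhm_to_sigma(grid$psf_fwhm_nm)^2) / px

  # vesicle records -----------------------------------------------------
  r_in <- geometry$nucleus_radius_nm
  r_out <- geometry$cell_radius_nm - geometry$membrane_thickness_nm
  n_coloc <- round(coloc_fraction * n_vesicles)
  if (is.null(n_marker_extra))
    n_marker_extra <- max(0L, n_vesicles - n_coloc)
  vesicles <- NULL
  if (n_vesicles > 0) {
    pos <- sample_annulus(n_vesicles, r_in, r_out)
    w <- stats::rlnorm(n_vesicles, -brightness_sdlog^2 / 2, brightness_sdlog)
    photons <- vesicle_photons_total * w / sum(w)
    flagged <- seq_len(n_vesicles) %in%
      sample.int(n_vesicles, n_coloc)
    vesicles <- data.frame(
      vesicle_id = seq_len(n_vesicles),
      y_nm = pos[, "y_nm"], x_nm = pos[, "x_nm"],
      y_px = center[1] + pos[, "y_nm"] / px,
      x_px = center[2] + pos[, "x_nm"] / px,
      photons = photons, colocalized = flagged)
  }
  marker_extra <- NULL
  if (n_marker_extra > 0) {
    pos <- sample_annulus(n_marker_extra, r_in, r_out)
    marker_extra <- data.frame(
      y_px = center[1] + pos[, "y_nm"] / px,
      x_px = center[2] + pos[, "x_nm"] / px)
  }

  # render ---------------------------------------------------------------
  ch1 <- render_ring(ny, nx, center,
                     (geometry$cell_radius_nm -
                      geometry$membrane_thickness_nm / 2) / px,
                     sigma_mem_px[1], membrane_photons)
  if (!is.null(vesicles))
    for (i in seq_len(nrow(vesicles)))
      ch1 <- add_spot(ch1, vesicles$y_px[i], vesicles$x_px[i],
                      sigma_spot_px[1], vesicles$photons[i])

  ch2 <- matrix(0, ny, nx)
  marker_spot_photons <- if (n_vesicles > 0)
    vesicle_photons_total / n_vesicles else photons_total * 0.05
  n_marker <- n_coloc + n_marker_extra
  marker_w <- if (n_marker > 0)
    stats::rlnorm(n_marker, -brightness_sdlog^2 / 2, brightness_sdlog)
    else numeric()
  mi <- 0L
  if (!is.null(vesicles))
    for (i in which(vesicles$colocalized)) {
      mi <- mi + 1L
      ch2 <- add_spot(ch2, vesicles$y_px[i], vesicles$x_px[i],
                      sigma_spot_px[2], marker_spot_photons * marker_w[mi])
    }
  if (!is.null(marker_extra))
    for (i in seq_len(nrow(marker_extra))) {
      mi <- mi + 1L
      ch2 <- add_spot(ch2, marker_extra$y_px[i], marker_extra$x_px[i],
                      sigma_spot_px[2], marker_spot_photons * marker_w[mi])
    }

  if (noise) {
    ch1 <- apply_noise(ch1, offset, read_sd)
    ch2 <- apply_noise(ch2, offset, read_sd)
  } else {
    ch1 <- ch1 + offset
    ch2 <- ch2 + offset
  }

  data <- array(0, dim = c(1, 1, 2, ny, nx))
  data[1, 1, 1, , ] <- ch1
  data[1, 1, 2, , ] <- ch2
  stack <- image_stack(data, px, grid$channel_names[1:2],
                       grid$frame_interval_s, grid$psf_fwhm_nm[1:2])

  truth <- simulation_truth(
    kind = "cell_image",
    vesicles = vesicles,
    params = list(geometry = unclass(geometry),
                  grid = unclass(grid),
                  kinetics = unclass(kinetics), quench = unclass(quench),
                  t_min = t_min, quenched = quenched,
                  n_vesicles = n_vesicles, coloc_fraction = coloc_fraction,
                  n_marker_extra = n_marker_extra,
                  vesicle_fwhm_nm = vesicle_fwhm_nm,
                  photons_total = photons_total, noise = noise,
                  offset = offset, read_sd = read_sd),
    seed = seed,
    center_px = center,
    membrane_photons = membrane_photons,
    vesicle_photons_total = vesicle_photons_total,
    marker_photons_total = marker_spot_photons * sum(marker_w),
    marker_extra = marker_extra,
    rendered_sigma_px = sigma_spot_px)
  list(stack = stack, truth = truth)
}
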