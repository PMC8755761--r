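#' Acquisition grid: pixels, channels, timing, optics
#'
#' Describes how a synthetic scene is sampled: physical pixel size, array
#' extents in TZYX order, channel labels, frame interval and the per-channel
#' point-spread-function FWHM. The PSF is modelled as an isotropic Gaussian;
#' a PSF FWHM below the pixel size means the optics are under-sampled and
#' triggers a warning (the spot would live in a single pixel).
#'
#' @param pixel_size_nm physical pixel size, nm/pixel (> 0).
#' @param shape named or unnamed integer vector `(t, z, y, x)`.
#' @param channel_names character vector of channel labels.
#' @param frame_interval_s time between frames, seconds.
#' @param psf_fwhm_nm per-channel PSF FWHM, nm (recycled to n channels).
#' @return object of class `acquisition_grid`.
#' @export
acquisition_grid <- function(pixel_size_nm = 80,
                             shape = c(t = 1, z = 1, y = 192, x = 192),
                             channel_names = c("antigen", "marker"),
                             frame_interval_s = 5,
                             psf_fwhm_nm = 250) {
  stopifnot(pixel_size_nm > 0, length(shape) == 4, all(shape >= 1),
            length(channel_names) >= 1, frame_interval_s > 0,
            all(psf_fwhm_nm > 0))
  shape <- as.integer(shape)
  names(shape) <- c("t", "z", "y", "x")
  psf_fwhm_nm <- rep_len(psf_fwhm_nm, length(channel_names))
  if (any(psf_fwhm_nm < pixel_size_nm))
    warning("PSF FWHM below pixel size: the image is under-sampled")
  structure(list(pixel_size_nm = pixel_size_nm, shape = shape,
                 channel_names = channel_names,
                 frame_interval_s = frame_interval_s,
                 psf_fwhm_nm = psf_fwhm_nm),
            class = "acquisition_grid")
}

#' Idealized round-cell geometry
#'
#' A lymphocyte-like cell: a disc of radius `cell_radius_nm` whose nucleus
#' (radius `nucleus_radius_nm`) leaves only a thin cytoplasmic annulus, plus
#' a membrane shell of thickness `membrane_thickness_nm`. Vesicles are
#' placed only in the cytoplasmic annulus between the nucleus and the inner
#' membrane face. The default nucleus radius is about 89\% of the cell
#' radius, i.e. a nucleus filling ~70\% of the cell volume as is typical
#' for B cells.
#'
#' @param center_px `(y, x)` center in 0-based pixel coordinates, or `NULL`
#'   for the grid center.
#' @param cell_radius_nm cell radius, nm.
#' @param nucleus_radius_nm nucleus radius, nm (< cell radius).
#' @param membrane_thickness_nm membrane shell thickness, nm.
#' @return object of class `cell_geometry`.
#' @export
cell_geometry <- function(center_px = NULL, cell_radius_nm = 5000,
                          nucleus_radius_nm = round(0.7^(1 / 3) * cell_radius_nm),
                          membrane_thickness_nm = 100) {
  stopifnot(cell_radius_nm > 0, nucleus_radius_nm >= 0,
            membrane_thickness_nm > 0)
  if (nucleus_radius_nm >= cell_radius_nm)
    stop("nucleus_radius_nm must be smaller than cell_radius_nm")
  if (nucleus_radius_nm >= cell_radius_nm - membrane_thickness_nm)
    stop("no cytoplasmic annulus: nucleus reaches the membrane")
  structure(list(center_px = center_px, cell_radius_nm = cell_radius_nm,
                 nucleus_radius_nm = nucleus_radius_nm,
                 membrane_thickness_nm = membrane_thickness_nm),
            class = "cell_geometry")
}

#' Multi-channel image stack with physical metadata
#'
#' Thin container for a 5-D intensity array in `(t, z, c, y, x)` order plus
#' the acquisition metadata needed to interpret it physically. Singleton
#' axes are kept, so a single 2-channel 2-D image has dim `(1, 1, 2, y, x)`.
#'
#' @param data numeric 5-D array, dim `(t, z, c, y, x)`.
#' @param pixel_size_nm nm per pixel.
#' @param channel_names channel labels, length = dim(data)\[3\].
#' @param frame_interval_s seconds between frames.
#' @param psf_fwhm_nm per-channel PSF FWHM (nm), metadata only.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_nm, channel_names = NULL,
                        frame_interval_s = NA_real_, psf_fwhm_nm = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 5, pixel_size_nm > 0)
  nc <- dim(data)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  stopifnot(length(channel_names) == nc)
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 channel_names = channel_names,
                 frame_interval_s = frame_interval_s,
                 psf_fwhm_nm = psf_fwhm_nm),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_stack: t=%d z=%d c=%d y=%d x=%d, %.3g nm/px, channels: %s\n",
    d[1], d[2], d[3], d[4], d[5], x$pixel_size_nm,
    paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Extract one 2-D plane from an image stack
#'
#' @param stack an [image_stack()].
#' @param t,z,c 1-based frame, slice and channel indices. `c` may be a
#'   channel name.
#' @return numeric matrix (y, x).
#' @export
stack_plane <- function(stack, t = 1, z = 1, c = 1) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(c)) c <- match(c, stack$channel_names)
  stack$data[t, z, c, , ]
}

# FWHM of a Gaussian = 2 sqrt(2 ln 2) sigma
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

fwhm_to_sigma <- function(fwhm) fwhm / FWHM_SIGMA
sigma_to_fwhm <- function(sigma) sigma * FWHM_SIGMA
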