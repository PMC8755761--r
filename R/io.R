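# On-disk formats:
#   images      -> multi-page 16-bit TIFF, pages in T-Z-C raster order
#                  (axes TZCYX), plus a JSON sidecar <basename>.json with
#                  pixel size, axis order, channel names, intensity scale
#                  and any ground truth.
#   flow tables -> CSV: cell_id, timepoint_min, quenched, replicate,
#                  intensity, group.

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are emitted in TZCYX raster order (channel fastest). Intensities
#' are stored as 16-bit integers after scaling by `65535 / max`; the scale
#' factor and all physical metadata go into the sidecar so readers can
#' reconstruct intensities exactly up to the 16-bit quantization.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar gets the same basename with
#'   extension `.json`.
#' @param truth optional `simulation_truth` serialized into the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, truth = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  vmax <- max(stack$data, 1e-12)
  pages <- list()
  for (ti in seq_len(d[1]))
    for (zi in seq_len(d[2]))
      for (ci in seq_len(d[3]))
        pages[[length(pages) + 1L]] <-
          pmin(pmax(stack$data[ti, zi, ci, , ] / vmax, 0), 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    axes = "TZCYX",
    shape = list(t = d[1], z = d[2], c = d[3], y = d[4], x = d[5]),
    pixel_size_nm = stack$pixel_size_nm,
    frame_interval_s = stack$frame_interval_s,
    channel_names = stack$channel_names,
    psf_fwhm_nm = stack$psf_fwhm_nm,
    intensity_scale = vmax / 65535)
  if (!is.null(truth)) meta$truth <- truth_to_list(truth)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path with its `.json` sidecar next to it.
#' @return an [image_stack()]; intensities rescaled to their original
#'   values (16-bit quantization aside). The sidecar list is attached as
#'   attribute `"sidecar"`.
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sh <- meta$shape
  data <- array(0, dim = c(sh$t, sh$z, sh$c, sh$y, sh$x))
  k <- 0L
  scale <- meta$intensity_scale * 65535
  for (ti in seq_len(sh$t))
    for (zi in seq_len(sh$z))
      for (ci in seq_len(sh$c)) {
        k <- k + 1L
        data[ti, zi, ci, , ] <- pages[[k]] * scale
      }
  st <- image_stack(data, meta$pixel_size_nm, meta$channel_names,
                    meta$frame_interval_s, meta$psf_fwhm_nm)
  attr(st, "sidecar") <- meta
  st
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

truth_to_list <- function(truth) {
  x <- unclass(truth)
  x[!vapply(x, is.null, logical(1))]
}

#' Write / read a per-cell flow-cytometry table
#'
#' Plain CSV with the columns cell_id, timepoint_min, quenched, replicate,
#' intensity and group. [write_flow_table()] can attach the simulation
#' truth as a JSON sidecar.
#'
#' @param table the flow table data.frame.
#' @param path CSV path.
#' @param truth optional `simulation_truth` written to a `.json` sidecar.
#' @return `path` invisibly (write) or the data.frame (read).
#' @export
write_flow_table <- function(table, path, truth = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth_to_list(truth),
                         paste0(sub("\\.csv$", "", path), ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_flow_table
#' @export
read_flow_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
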