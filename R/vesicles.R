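# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma_px) {
  h <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-h:h, sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    padded <- rbind(m[rep(1L, h), , drop = FALSE], m,
                    m[rep(n, h), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# scale-normalized Laplacian-of-Gaussian response, positive at bright blobs
log_response <- function(img, sigma_px) {
  g <- gaussian_blur(img, sigma_px)
  n <- nrow(g); m <- ncol(g)
  up    <- g[c(1L, 1:(n - 1L)), ]
  down  <- g[c(2:n, n), ]
  left  <- g[, c(1L, 1:(m - 1L))]
  right <- g[, c(2:m, m)]
  -sigma_px^2 * (up + down + left + right - 4 * g)
}

#' Detect diffraction-limited spots with a Laplacian-of-Gaussian filter
#'
#' Computes the scale-normalized LoG response at the detection scale
#' `sigma = scale_nm / (2 sqrt(2 ln 2)) / pixel_size`, keeps strict 3x3
#' local maxima whose response exceeds `median + threshold_k * MAD` of the
#' response image, and refines each maximum to sub-pixel precision with a
#' separable quadratic fit. A detection scale below the sampling limit
#' (one pixel) is clamped with a warning.
#'
#' @param image numeric matrix, or an [image_stack()] (use `t`, `z`, `c`).
#' @param pixel_size_nm nm per pixel (taken from the stack if given one).
#' @param scale_nm expected spot FWHM (structure + PSF), nm.
#' @param threshold_k robust threshold multiplier on the response MAD.
#' @param t,z,c plane selectors when `image` is a stack.
#' @return data.frame of class `spot_list`: y_px, x_px (0-based, sub-pixel),
#'   peak (raw image value at the maximum), response, sigma_px, frame.
#' @export
detect_spots <- function(image, scale_nm = 250, threshold_k = 8,
                         pixel_size_nm = NULL, t = 1, z = 1, c = 1) {
  if (inherits(image, "image_stack")) {
    pixel_size_nm <- image$pixel_size_nm
    image <- stack_plane(image, t, z, c)
  }
  stopifnot(is.matrix(image), !is.null(pixel_size_nm), pixel_size_nm > 0)
  sigma_px <- fwhm_to_sigma(scale_nm) / pixel_size_nm
  if (sigma_px < 1) {
    warning("detection scale below the sampling limit; clamped to 1 px")
    sigma_px <- 1
  }
  resp <- log_response(image, sigma_px)
  thr <- stats::median(resp) + threshold_k * stats::mad(resp)

  n <- nrow(resp); m <- ncol(resp)
  best <- resp >= thr
  # strict local maximum over the 8-neighborhood (interior pixels only)
  is_max <- matrix(FALSE, n, m)
  core <- 2:(n - 1)
  corj <- 2:(m - 1)
  r <- resp[core, corj]
  is_max[core, corj] <-
    r > resp[core - 1, corj]     & r > resp[core + 1, corj] &
    r > resp[core, corj - 1]     & r > resp[core, corj + 1] &
    r > resp[core - 1, corj - 1] & r > resp[core - 1, corj + 1] &
    r > resp[core + 1, corj - 1] & r > resp[core + 1, corj + 1]
  peaks <- which(best & is_max, arr.ind = TRUE)
  if (nrow(peaks) == 0)
    return(empty_spot_list(sigma_px, t))

  refine <- function(i, j) {
    # per-axis quadratic interpolation of the response
    dy <- quad_offset(resp[i - 1, j], resp[i, j], resp[i + 1, j])
    dx <- quad_offset(resp[i, j - 1], resp[i, j], resp[i, j + 1])
    c(i - 1 + dy, j - 1 + dx)          # 0-based
  }
  pos <- t(mapply(refine, peaks[, 1], peaks[, 2]))
  spots <- data.frame(
    y_px = pos[, 1], x_px = pos[, 2],
    peak = image[peaks],
    response = resp[peaks],
    sigma_px = sigma_px,
    frame = t)
  spots <- spots[order(-spots$response), ]
  rownames(spots) <- NULL
  class(spots) <- c("spot_list", "data.frame")
  spots
}

quad_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (den >= 0) return(0)              # not a proper maximum
  off <- 0.5 * (fm - fp) / den
  max(-0.5, min(0.5, off))
}

empty_spot_list <- function(sigma_px, frame) {
  s <- data.frame(y_px = numeric(), x_px = numeric(), peak = numeric(),
                  response = numeric(), sigma_px = numeric(),
                  frame = integer())
  class(s) <- c("spot_list", "data.frame")
  s
}

#' Background-subtracted mean fluorescence intensity of a cell ROI
#'
#' Sum-projects the z axis when present, measures the mean intensity in a
#' circular cell ROI, and subtracts the mean of `n_background` seeded
#' random circular background ROIs placed outside every cell ROI. The
#' background sampling is reproducible from `seed` (recorded in the
#' result). A corrected MFI below zero is possible with noisy backgrounds
#' and is flagged rather than clipped.
#'
#' @param image matrix or [image_stack()]; stacks are sum-projected over z.
#' @param center_px cell ROI center `(y, x)`, 0-based pixels.
#' @param diameter_px cell ROI diameter, pixels (circular ROI).
#' @param all_cell_centers optional list/matrix of all cell centers to
#'   exclude from background sampling (defaults to the one measured cell).
#' @param n_background number of background ROIs.
#' @param bg_diameter_px background ROI diameter, pixels.
#' @param seed RNG seed for background placement.
#' @param t,c plane selectors for stacks.
#' @return list of class `mfi_result`: roi_mean, background_mean,
#'   background_positions (data.frame), corrected, negative (flag), seed.
#' @export
measure_mfi <- function(image, center_px, diameter_px = 100,
                        all_cell_centers = NULL, n_background = 4,
                        bg_diameter_px = 30, seed = 1, t = 1, c = 1) {
  if (inherits(image, "image_stack")) {
    nz <- dim(image$data)[2]
    img <- stack_plane(image, t, 1, c)
    if (nz > 1)
      for (z in 2:nz) img <- img + stack_plane(image, t, z, c)
  } else img <- image
  stopifnot(is.matrix(img), length(center_px) == 2)
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(all_cell_centers)) all_cell_centers <- list(center_px)
  if (is.matrix(all_cell_centers))
    all_cell_centers <- split(all_cell_centers, seq_len(nrow(all_cell_centers)))

  disc_mean <- function(cy, cx, radius) {
    d2 <- outer((0:(ny - 1) - cy)^2, (0:(nx - 1) - cx)^2, "+")
    sel <- d2 <= radius^2
    if (!any(sel)) stop("ROI falls outside the image")
    mean(img[sel])
  }
  roi_mean <- disc_mean(center_px[1], center_px[2], diameter_px / 2)

  local_rng(seed)
  r_bg <- bg_diameter_px / 2
  r_cell <- diameter_px / 2
  placed <- list()
  tries <- 0L
  while (length(placed) < n_background) {
    tries <- tries + 1L
    if (tries > 2000L)
      stop("cannot place ", n_background,
           " non-overlapping background ROIs outside the cell ROIs")
    cy <- stats::runif(1, r_bg, ny - 1 - r_bg)
    cx <- stats::runif(1, r_bg, nx - 1 - r_bg)
    clear_cells <- all(vapply(all_cell_centers, function(cc)
      sqrt((cy - cc[1])^2 + (cx - cc[2])^2) > r_cell + r_bg, logical(1)))
    clear_prev <- all(vapply(placed, function(p)
      sqrt((cy - p[1])^2 + (cx - p[2])^2) > bg_diameter_px, logical(1)))
    if (clear_cells && clear_prev) placed[[length(placed) + 1L]] <- c(cy, cx)
  }
  bg_means <- vapply(placed, function(p) disc_mean(p[1], p[2], r_bg),
                     numeric(1))
  corrected <- roi_mean - mean(bg_means)
  structure(list(
    roi_mean = roi_mean,
    background_mean = mean(bg_means),
    background_positions = data.frame(
      y_px = vapply(placed, `[`, numeric(1), 1),
      x_px = vapply(placed, `[`, numeric(1), 2),
      mean = bg_means),
    corrected = corrected,
    negative = corrected < 0,
    seed = seed), class = "mfi_result")
}

#' Intensity profile along a line segment
#'
#' Bilinear interpolation of the image along the segment `p0 -> p1`, at a
#' spacing of at most `sampling_px` pixels, with physical coordinates in nm
#' measured from `p0`.
#'
#' @param image matrix or [image_stack()].
#' @param p0,p1 segment endpoints `(y, x)` in 0-based pixels.
#' @param pixel_size_nm nm per pixel (from the stack if given one).
#' @param sampling_px sample spacing along the line, pixels.
#' @param t,z,c plane selectors for stacks.
#' @return data.frame: distance_nm, intensity, y_px, x_px.
#' @export
line_profile <- function(image, p0, p1, pixel_size_nm = NULL,
                         sampling_px = 0.5, t = 1, z = 1, c = 1) {
  if (inherits(image, "image_stack")) {
    pixel_size_nm <- image$pixel_size_nm
    image <- stack_plane(image, t, z, c)
  }
  stopifnot(is.matrix(image), !is.null(pixel_size_nm),
            length(p0) == 2, length(p1) == 2, sampling_px > 0)
  len_px <- sqrt(sum((p1 - p0)^2))
  if (len_px == 0) stop("zero-length profile line")
  ny <- nrow(image); nx <- ncol(image)
  inside <- function(p) all(p >= 0) && p[1] <= ny - 1 && p[2] <= nx - 1
  if (!inside(p0) || !inside(p1)) stop("profile endpoints outside the image")
  n_samples <- max(2L, ceiling(len_px / sampling_px) + 1L)
  s <- seq(0, 1, length.out = n_samples)
  ys <- p0[1] + s * (p1[1] - p0[1])
  xs <- p0[2] + s * (p1[2] - p0[2])
  data.frame(distance_nm = s * len_px * pixel_size_nm,
             intensity = bilinear(image, ys, xs),
             y_px = ys, x_px = xs)
}

bilinear <- function(img, ys, xs) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- pmin(pmax(floor(ys), 0), ny - 2)
  x0 <- pmin(pmax(floor(xs), 0), nx - 2)
  fy <- ys - y0; fx <- xs - x0
  i <- y0 + 1L; j <- x0 + 1L
  img[cbind(i, j)]         * (1 - fy) * (1 - fx) +
    img[cbind(i + 1, j)]     * fy       * (1 - fx) +
    img[cbind(i, j + 1)]     * (1 - fy) * fx +
    img[cbind(i + 1, j + 1)] * fy       * fx
}

#' Gaussian fit of an intensity profile and its FWHM
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 sigma^2)) + B` to a line
#' profile; the apparent structure diameter is the full width at half
#' maximum `2 sqrt(2 ln 2) * sigma`. Initial values come from the peak and
#' its half-maximum crossings; the fit window is limited to `fit_window_k`
#' initial sigmas around the peak so neighbouring structures do not bias
#' the fit. Failures and poor fits (r-squared below `min_r_squared`) are
#' returned flagged — never a silent number.
#'
#' @param profile data.frame from [line_profile()] (columns distance_nm,
#'   intensity), or a numeric vector with `x_nm` supplied.
#' @param x_nm coordinates when `profile` is a bare vector.
#' @param fit_window_k half-width of the fit window, in initial sigmas.
#' @param min_r_squared below this r-squared the result is flagged.
#' @return list of class `fwhm_result`: amplitude, center_nm, sigma_nm,
#'   baseline, fwhm_nm, residual_norm, r_squared, ok.
#' @export
fit_gaussian_fwhm <- function(profile, x_nm = NULL, fit_window_k = 3,
                              min_r_squared = 0.5) {
  if (is.data.frame(profile)) {
    x <- profile$distance_nm
    y <- profile$intensity
  } else {
    x <- x_nm
    y <- as.numeric(profile)
  }
  stopifnot(length(x) == length(y))
  if (length(y) < 5) stop("need at least 5 profile samples")
  bad <- function() list(amplitude = NA_real_, center_nm = NA_real_,
                         sigma_nm = NA_real_, baseline = NA_real_,
                         fwhm_nm = NA_real_, residual_norm = NA_real_,
                         r_squared = NA_real_, ok = FALSE)
  if (stats::sd(y) < 1e-12) return(structure(bad(), class = "fwhm_result"))

  # init: peak, baseline from profile ends, sigma from half-max width
  i_max <- which.max(y)
  B0 <- min(mean(y[seq_len(max(1, length(y) %/% 10))]),
            mean(y[seq(length(y) - max(1, length(y) %/% 10) + 1, length(y))]))
  A0 <- y[i_max] - B0
  half <- B0 + A0 / 2
  above <- y >= half
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ri <- which(runs$values & starts <= i_max & ends >= i_max)
  if (length(ri) == 1) {
    w <- x[min(ends[ri], length(x))] - x[starts[ri]]
    s0 <- max(w / FWHM_SIGMA, diff(range(x)) / length(x))
  } else s0 <- diff(range(x)) / 6
  mu0 <- x[i_max]

  keep <- abs(x - mu0) <= fit_window_k * s0
  if (sum(keep) < 5) keep <- rep(TRUE, length(x))
  xx <- x[keep]; yy <- y[keep]

  gauss <- function(p) p[1] * exp(-(xx - p[2])^2 / (2 * p[3]^2)) + p[4]
  jac <- function(p) {
    e <- exp(-(xx - p[2])^2 / (2 * p[3]^2))
    cbind(-e,
          -p[1] * e * (xx - p[2]) / p[3]^2,
          -p[1] * e * (xx - p[2])^2 / p[3]^3,
          -1)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = A0, mu = mu0, s = s0, B = B0),
      fn = function(p) yy - gauss(p),
      jac = jac,
      lower = c(A = 0, mu = min(xx), s = 1e-6, B = -Inf),
      upper = c(A = Inf, mu = max(xx), s = diff(range(xx)) * 10, B = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$deviance))
    return(structure(bad(), class = "fwhm_result"))
  cf <- fit$par
  res <- fit$fvec
  ss_tot <- sum((yy - mean(yy))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(
    amplitude = unname(cf["A"]), center_nm = unname(cf["mu"]),
    sigma_nm = unname(cf["s"]), baseline = unname(cf["B"]),
    fwhm_nm = sigma_to_fwhm(unname(cf["s"])),
    residual_norm = sqrt(sum(res^2)),
    r_squared = r2,
    ok = is.finite(r2) && r2 >= min_r_squared),
    class = "fwhm_result")
}

#' @export
print.fwhm_result <- function(x, ...) {
  if (x$ok)
    cat(sprintf("fwhm_result: FWHM %.1f nm (sigma %.1f nm, r^2 %.3f)\n",
                x$fwhm_nm, x$sigma_nm, x$r_squared))
  else cat("fwhm_result: fit failed or poor (flagged)\n")
  invisible(x)
}

#' Apparent vesicle sizes per condition from line-profile FWHM
#'
#' For each condition (an image plus its detected or ground-truth spots),
#' measures the apparent diameter of the brightest `n_per_condition`
#' vesicles: a horizontal line profile through each sub-pixel spot center,
#' a Gaussian fit, and its FWHM. Mirrors the 5-10-vesicles-per-condition
#' convention; a condition with fewer usable vesicles is still reported,
#' with a warning.
#'
#' @param conditions named list; each element a list with `image` (matrix
#'   or [image_stack()]), `spots` (a `spot_list` or data.frame with
#'   y_px/x_px), and optionally `pixel_size_nm`.
#' @param n_per_condition vesicles to size per condition.
#' @param profile_halfwidth_px half-length of the profile line, pixels.
#' @return list with `per_vesicle` (condition, vesicle, fwhm_nm, r_squared,
#'   ok) and `summary` (condition, n, mean_fwhm_nm, sd_fwhm_nm).
#' @export
vesicle_size_report <- function(conditions, n_per_condition = 10,
                                profile_halfwidth_px = 8) {
  stopifnot(is.list(conditions), length(conditions) >= 1)
  if (is.null(names(conditions)))
    names(conditions) <- paste0("condition_", seq_along(conditions))
  per <- list()
  for (cname in names(conditions)) {
    cond <- conditions[[cname]]
    img <- cond$image
    psz <- cond$pixel_size_nm
    if (inherits(img, "image_stack")) {
      psz <- img$pixel_size_nm
      img <- stack_plane(img)
    }
    spots <- cond$spots
    if (nrow(spots) < 5)
      warning("condition ", cname, " has fewer than 5 vesicles (",
              nrow(spots), "); reported anyway")
    n_take <- min(n_per_condition, nrow(spots))
    for (i in seq_len(n_take)) {
      y <- spots$y_px[i]; x <- spots$x_px[i]
      x0 <- max(0, x - profile_halfwidth_px)
      x1 <- min(ncol(img) - 1, x + profile_halfwidth_px)
      prof <- line_profile(img, c(y, x0), c(y, x1), pixel_size_nm = psz)
      fit <- fit_gaussian_fwhm(prof)
      per[[length(per) + 1L]] <- data.frame(
        condition = cname, vesicle = i,
        fwhm_nm = fit$fwhm_nm, r_squared = fit$r_squared, ok = fit$ok)
    }
  }
  per_vesicle <- do.call(rbind, per)
  ok <- per_vesicle[per_vesicle$ok %in% TRUE, ]
  summary <- do.call(rbind, lapply(split(ok, ok$condition), function(d)
    data.frame(condition = d$condition[1], n = nrow(d),
               mean_fwhm_nm = mean(d$fwhm_nm),
               sd_fwhm_nm = stats::sd(d$fwhm_nm))))
  rownames(summary) <- NULL
  list(per_vesicle = per_vesicle, summary = summary)
}
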