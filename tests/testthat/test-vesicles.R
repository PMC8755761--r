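test_that("a blank image yields no detections", {
  expect_equal(nrow(detect_spots(matrix(7, 96, 96), scale_nm = 250,
                                 pixel_size_nm = 80)), 0)
})

test_that("a single rendered spot is found at sub-pixel accuracy", {
  sim <- simulate_cell_image(
    cell_geometry(cell_radius_nm = 4000),
    acquisition_grid(pixel_size_nm = 40, shape = c(1, 1, 256, 256),
                     psf_fwhm_nm = 250),
    quench = quench_model(efficiency_q = 1), quenched = TRUE,
    n_vesicles = 1, coloc_fraction = 0, vesicle_fwhm_nm = 100,
    noise = FALSE, seed = 3)
  sp <- detect_spots(sim$stack, scale_nm = 270)
  v <- sim$truth$vesicles
  expect_equal(nrow(sp), 1)
  expect_lt(sqrt((sp$y_px - v$y_px)^2 + (sp$x_px - v$x_px)^2), 0.5)
})

test_that("well-separated bright spots are detected with perfect recall and precision", {
  set.seed(50)
  sigma <- 2.5
  ny <- nx <- 160
  # >= 4 sigma separation enforced by rejection sampling
  centers <- matrix(numeric(0), 0, 2)
  while (nrow(centers) < 20) {
    p <- runif(2, 15, ny - 16)
    if (nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >
          4 * 2 * sigma)
      centers <- rbind(centers, p)
  }
  clean <- oracle_spot_field(ny, nx, centers, amplitude = 200,
                             sigma_px = sigma, baseline = 10)
  noisy <- matrix(rpois(ny * nx, clean), ny, nx)   # SNR ~ 200/sqrt(210) > 10
  sp <- detect_spots(noisy, scale_nm = sigma * 2 * sqrt(2 * log(2)) * 80,
                     pixel_size_nm = 80)
  # match detections to truth at a 2-px radius
  used <- rep(FALSE, nrow(centers))
  matched <- 0L
  for (k in seq_len(nrow(sp))) {
    dd <- sqrt((centers[, 1] - sp$y_px[k])^2 + (centers[, 2] - sp$x_px[k])^2)
    j <- which.min(dd)
    if (dd[j] <= 2 && !used[j]) { used[j] <- TRUE; matched <- matched + 1L }
  }
  expect_equal(matched, 20)            # recall 1
  expect_equal(nrow(sp), 20)           # precision 1
})

test_that("detection and sizing are invariant to whole-pixel shifts", {
  sigma <- 2
  base <- c(40.3, 52.7)
  img1 <- oracle_spot_field(96, 96, rbind(base), 150, sigma, baseline = 5)
  img2 <- oracle_spot_field(96, 96, rbind(base + c(7, -9)), 150, sigma,
                            baseline = 5)
  s1 <- detect_spots(img1, scale_nm = sigma * 2.3548 * 100,
                     pixel_size_nm = 100)
  s2 <- detect_spots(img2, scale_nm = sigma * 2.3548 * 100,
                     pixel_size_nm = 100)
  expect_equal(s2$y_px - s1$y_px, 7, tolerance = 1e-6)
  expect_equal(s2$x_px - s1$x_px, -9, tolerance = 1e-6)
  f1 <- fit_gaussian_fwhm(line_profile(img1, c(s1$y_px, s1$x_px - 10),
                                       c(s1$y_px, s1$x_px + 10), 100))
  f2 <- fit_gaussian_fwhm(line_profile(img2, c(s2$y_px, s2$x_px - 10),
                                       c(s2$y_px, s2$x_px + 10), 100))
  expect_equal(f1$fwhm_nm, f2$fwhm_nm, tolerance = 1e-6)
})

test_that("warnings fire below the sampling limit", {
  img <- oracle_spot_field(64, 64, rbind(c(32, 32)), 100, 2, baseline = 1)
  expect_warning(detect_spots(img, scale_nm = 50, pixel_size_nm = 80),
                 "sampling")
})

test_that("MFI is background-subtracted, seeded and reproducible", {
  # constant image: corrected MFI is exactly zero
  m0 <- measure_mfi(matrix(7, 256, 256), center_px = c(128, 128), seed = 4)
  expect_equal(m0$corrected, 0)
  expect_false(m0$negative)
  # cell of known mean signal on a constant offset
  d2 <- outer((0:255 - 128)^2, (0:255 - 128)^2, "+")
  img <- 20 + 50 * (d2 <= 30^2)
  m1 <- measure_mfi(img, center_px = c(128, 128), diameter_px = 100,
                    seed = 4)
  roi_truth <- mean(img[d2 <= 50^2]) - 20
  expect_equal(m1$corrected, roi_truth, tolerance = 1e-9)
  # same seed, same background positions; different seed, different ones
  m2 <- measure_mfi(img, center_px = c(128, 128), diameter_px = 100,
                    seed = 4)
  expect_identical(m1$background_positions, m2$background_positions)
  m3 <- measure_mfi(img, center_px = c(128, 128), diameter_px = 100,
                    seed = 5)
  expect_false(identical(m1$background_positions$y_px,
                         m3$background_positions$y_px))
  expect_equal(nrow(m1$background_positions), 4)
  # impossible placement -> error
  expect_error(measure_mfi(matrix(1, 40, 40), center_px = c(20, 20),
                           diameter_px = 100, seed = 1),
               "background ROIs")
})

test_that("line profiles interpolate bilinearly with physical coordinates", {
  img <- matrix(3, 50, 50)
  pr <- line_profile(img, c(10, 5), c(10, 45), pixel_size_nm = 65)
  expect_true(all(pr$intensity == 3))
  expect_equal(max(pr$distance_nm), 40 * 65)
  expect_lte(max(diff(pr$x_px)), 0.5 + 1e-12)
  expect_error(line_profile(img, c(10, 5), c(10, 5), pixel_size_nm = 65),
               "zero-length")
  expect_error(line_profile(img, c(-3, 5), c(10, 45), pixel_size_nm = 65),
               "outside")
  # profile through a rendered Gaussian peaks at the spot center, and an
  # off-center chord peaks lower
  spot <- oracle_spot_field(64, 64, rbind(c(31.5, 31.5)), 80, 3)
  pc <- line_profile(spot, c(31.5, 10), c(31.5, 53), pixel_size_nm = 100)
  expect_equal(pc$x_px[which.max(pc$intensity)], 31.5, tolerance = 0.5)
  po <- line_profile(spot, c(35.5, 10), c(35.5, 53), pixel_size_nm = 100)
  expect_lt(max(po$intensity), max(pc$intensity))
})

test_that("the Gaussian FWHM estimator is exact on closed-form input", {
  x <- seq(-600, 600, by = 10)
  f <- fit_gaussian_fwhm(5 * exp(-x^2 / (2 * 100^2)) + 2, x_nm = x)
  expect_true(f$ok)
  expect_equal(f$fwhm_nm, 2 * sqrt(2 * log(2)) * 100, tolerance = 1e-3)
  expect_equal(f$sigma_nm, 100, tolerance = 1e-3)
  expect_equal(f$fwhm_nm / f$sigma_nm, 2.3548, tolerance = 1e-4)
  # constant profile: flagged, never a silent value
  fc <- fit_gaussian_fwhm(rep(4, 30), x_nm = seq_len(30))
  expect_false(fc$ok)
  expect_true(is.na(fc$fwhm_nm))
  expect_error(fit_gaussian_fwhm(c(1, 2, 1), x_nm = 1:3), "5 profile")
})

test_that("apparent spot size follows the Gaussian quadrature law", {
  # point-like vesicle (100 nm) under PSFs 150-450 nm: apparent FWHM must
  # be sqrt(structure^2 + psf^2) within 5%
  for (psf in c(150, 250, 450)) {
    sim <- simulate_cell_image(
      cell_geometry(cell_radius_nm = 4000),
      suppressWarnings(
        acquisition_grid(pixel_size_nm = 40, shape = c(1, 1, 256, 256),
                         psf_fwhm_nm = psf)),
      quench = quench_model(efficiency_q = 1), quenched = TRUE,
      n_vesicles = 1, coloc_fraction = 0, vesicle_fwhm_nm = 100,
      noise = FALSE, seed = 11)
    v <- sim$truth$vesicles
    img <- stack_plane(sim$stack)
    pr <- line_profile(img, c(v$y_px, v$x_px - 20), c(v$y_px, v$x_px + 20),
                       pixel_size_nm = 40)
    fit <- fit_gaussian_fwhm(pr)
    expect_true(fit$ok)
    expect_equal(fit$fwhm_nm, sqrt(100^2 + psf^2), tolerance = 0.05)
  }
})

test_that("the size report summarizes per-condition FWHM and orders PSFs", {
  mk <- function(psf, seed) {
    sim <- simulate_cell_image(
      cell_geometry(cell_radius_nm = 4500),
      acquisition_grid(pixel_size_nm = 80, shape = c(1, 1, 160, 160),
                       psf_fwhm_nm = psf),
      quench = quench_model(efficiency_q = 1), quenched = TRUE, t_min = 30,
      n_vesicles = 7, coloc_fraction = 0, vesicle_fwhm_nm = 150,
      noise = FALSE, seed = seed)
    spots <- detect_spots(sim$stack, scale_nm = sqrt(150^2 + psf^2))
    list(image = sim$stack, spots = spots)
  }
  rep450 <- mk(450, 21)
  rep260 <- mk(260, 21)
  out <- vesicle_size_report(list(sdcm = rep450, srrf = rep260),
                             n_per_condition = 7)
  s <- out$summary
  expect_gt(s$mean_fwhm_nm[s$condition == "sdcm"],
            s$mean_fwhm_nm[s$condition == "srrf"])
  expect_equal(s$mean_fwhm_nm[s$condition == "sdcm"], sqrt(150^2 + 450^2),
               tolerance = 0.10)
  expect_equal(s$mean_fwhm_nm[s$condition == "srrf"], sqrt(150^2 + 260^2),
               tolerance = 0.10)
  # under-five-vesicle conditions warn but still report
  few <- list(image = rep450$image, spots = rep450$spots[1:3, ])
  expect_warning(out2 <- vesicle_size_report(list(few = few)), "fewer than 5")
  expect_equal(nrow(out2$per_vesicle), 3)
})
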