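# Centroiding, slope conversion and modal least-squares reconstruction.

test_that("thresholded center of mass locates injected spots", {
  g <- geom_micro()
  ppsa <- g$pixels_per_subaperture
  ras <- matrix(0, g$detector_side_px, g$detector_side_px)
  # Gaussian spot at a known sub-pixel position inside cell (2, 3)
  cx0 <- (3 + 0.5) * ppsa - 0.5 + 3.25
  cy0 <- (2 + 0.5) * ppsa - 0.5 - 1.5
  xs <- seq_len(g$detector_side_px) - 1
  ras <- outer(exp(-(xs - cy0)^2 / 4), exp(-(xs - cx0)^2 / 4))
  h <- shwfsr:::new_hartmannogram(ras, g)
  cent <- measure_centroids(h, threshold_fraction = 0)
  i <- which(cent$row == 2 & cent$col == 3)
  expect_lt(abs(cent$cx[i] - cx0), 0.05)
  expect_lt(abs(cent$cy[i] - cy0), 0.05)
  # an empty cell is invalid
  expect_false(cent$valid[cent$row == 7 & cent$col == 0])
  # two equal spots average to their midpoint (documented cross-talk)
  ras2 <- matrix(0, g$detector_side_px, g$detector_side_px)
  ras2[17, 3] <- 1; ras2[17, 11] <- 1
  cent2 <- measure_centroids(shwfsr:::new_hartmannogram(ras2, g),
                             threshold_fraction = 0, min_energy_frac = 0)
  i2 <- which(cent2$row == 1 & cent2$col == 0)
  expect_equal(cent2$cx[i2], (2 + 10) / 2)
  expect_equal(cent2$cy[i2], 16)
  expect_error(measure_centroids(h, threshold_fraction = 1), "\\[0, 1\\)")
})

test_that("centroid displacements convert to slopes with the standard scale", {
  g <- geom_micro()
  cent <- tibble::tibble(row = 0, col = 0, dx_px = 1, dy_px = 0)
  sl <- slopes_from_centroids(cent, g)
  expect_equal(sl$sx, g$pixel_pitch * (g$pupil_diameter / 2) /
                 (g$focal_length * g$wavelength))
  expect_equal(sl$sy, 0)
  cent0 <- tibble::tibble(row = 0:1, col = 0:1, dx_px = 0, dy_px = 0)
  sl0 <- slopes_from_centroids(cent0, g)
  expect_equal(sl0$sx, c(0, 0))
})

test_that("the modal matrix has constant tilt columns and full rank", {
  mm <- mm_mini()
  nc <- nrow(mm$cells)
  tiltx <- mm$matrix[1:nc, 2]          # x-gradient of the x-tilt mode
  expect_lt(diff(range(tiltx)), 1e-10)
  expect_equal(qr(mm$matrix)$rank, 44)
  expect_lt(mm$condition, 100)
  expect_error(build_modal_matrix(geom_mini(), modes = 1:44, subgrid = 3),
               NA)  # coarser subgrid still builds
})

test_that("modal fit recovers single modes from analytic slopes", {
  g <- geom_mini()
  mm <- mm_mini()
  for (j in c(4, 7, 12)) {
    o <- spot_displacement_oracle(unit_coeffs(j), g)
    o$valid <- TRUE
    sl <- slopes_from_centroids(o, g)
    est <- modal_reconstruct(sl, mm)
    expect_equal(unname(est[j]), 1, tolerance = 0.01)
    expect_lt(max(abs(est[-j])), 0.01)
  }
  # zero slopes give zero coefficients
  o0 <- spot_displacement_oracle(rep(0, 44), g)
  o0$valid <- TRUE
  est0 <- modal_reconstruct(slopes_from_centroids(o0, g), mm)
  expect_equal(max(abs(est0)), 0)
})

test_that("few valid cells flag a low-confidence fit instead of erroring", {
  g <- geom_mini()
  mm <- mm_mini()
  o <- spot_displacement_oracle(unit_coeffs(4), g)
  o$valid <- FALSE
  o$valid[1:5] <- TRUE
  sl <- slopes_from_centroids(o, g)
  est <- modal_reconstruct(sl, mm)
  expect_true(attr(est, "low_confidence"))
})

test_that("the full pipeline closes the loop on a rendered defocus", {
  g <- geom_mini()
  h <- render_cached("mini_defoc1", unit_coeffs(4), g)
  est <- reconstruct_modal(h, mm_mini())
  expect_lt(residual_rms(unit_coeffs(4), est), 0.02)
})

test_that("defocus estimates are unbiased under small read noise", {
  g <- geom_micro()
  mm <- mm_micro()
  co <- unit_coeffs(4, 0.8)
  h <- render_cached("micro_defoc08", co, g)
  errs <- vapply(1:10, function(s) {
    hn <- shwfsr:::apply_sensor_noise(h, list(read_noise_sd = 2e-4 * max(h$intensity)),
                                      seed = s)
    unname(reconstruct_modal(hn, mm)[4]) - 0.8
  }, numeric(1))
  se <- stats::sd(errs) / sqrt(length(errs))
  bias_tol <- max(3 * se, 0.01)  # allow the small deterministic centroid bias
  expect_lt(abs(mean(errs)), bias_tol)
})

test_that("residual RMS follows the orthonormal-coefficient identity", {
  a <- sample_eye_coeffs(default_eye_model(), 2, seed = 1)
  expect_equal(residual_rms(a, a), c(0, 0))
  b <- a; b[1, 4] <- b[1, 4] + 0.1
  expect_equal(residual_rms(a, b)[1], 0.1, tolerance = 1e-12)
  # tilt exclusion
  b2 <- a; b2[1, 1] <- b2[1, 1] + 5
  expect_equal(residual_rms(a, b2)[1], 0)
  expect_equal(residual_rms(a, b2, exclude_tilt = FALSE)[1], 5)
  # batch summary with both SD conventions
  true <- matrix(0, 2, 44)
  est <- true; est[1, 4] <- 0.1; est[2, 4] <- 0.3
  s_pop <- residual_summary(true, est)
  expect_equal(s_pop$rmse_mean, 0.2)
  expect_equal(s_pop$rmse_sd, 0.1)
  s_smp <- residual_summary(true, est, sd_type = "sample")
  expect_equal(s_smp$rmse_sd, 0.1414, tolerance = 1e-3)
})
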