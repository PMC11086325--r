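# Sensor geometry and the physical-optics forward chain.

test_that("geometry derives the raster bookkeeping and validates inputs", {
  g <- shwfs_geometry()
  expect_equal(g$detector_side_px, 920)
  expect_equal(g$pixels_per_subaperture, 46)
  expect_equal(g$aperture_side, 6e-3, tolerance = 1e-12)
  g1 <- shwfs_geometry(pupil_diameter_mm = 0.3, lenslet_count = 1,
                       lenslet_pitch_um = 300, pixel_pitch_um = 300)
  expect_equal(g1$pixels_per_subaperture, 1)
  expect_error(shwfs_geometry(pixel_pitch_um = 7), "0.01 px")
  expect_error(shwfs_geometry(focal_length_mm = -15), "positive")
  expect_error(shwfs_geometry(pupil_diameter_mm = 10), "exceeds")
})

test_that("pupil field is a unit-modulus masked phase map, periodic in whole waves", {
  g <- geom_micro()
  f0 <- pupil_field(rep(0, 44), g)
  expect_true(all(Im(f0$u) == 0))
  vals <- unique(round(Re(f0$u), 12))
  expect_setequal(vals, c(0, 1))
  mask_n <- sum(Re(f0$u) == 1)
  expect_equal(sum(abs(f0$u)^2), mask_n)
  # adding a whole wave to W leaves the complex field unchanged (2 pi phase)
  set.seed(2)
  w <- matrix(rnorm(100), 10)
  u1 <- complex(modulus = 1, argument = 2 * pi * w)
  u2 <- complex(modulus = 1, argument = 2 * pi * (w + 1))
  expect_equal(u1, u2, tolerance = 1e-12)
  # aberrated pupil field stays unit-modulus inside the mask
  fA <- pupil_field(unit_coeffs(2, 0.25), g)
  expect_equal(abs(fA$u[fA$u != 0]), rep(1, sum(fA$u != 0)), tolerance = 1e-12)
})

test_that("the Fresnel propagator is unitary and matches the Gaussian pair", {
  n <- 256; pitch <- 5e-6; lam <- 840e-9; zd <- 0.015
  xv <- (seq_len(n) - (n + 1) / 2) * pitch
  w0 <- 2.5e-4
  u <- outer(exp(-xv^2 / w0^2), exp(-xv^2 / w0^2))
  u2 <- shwfsr:::propagate_field(u, pitch, lam, zd)
  expect_equal(sum(abs(u2)^2), sum(abs(u)^2), tolerance = 1e-6)
  expect_equal(Mod(shwfsr:::propagate_field(u * 0, pitch, lam, zd)), u * 0)
  # closed-form beam expansion: w(z) = w0 sqrt(1 + (z / zR)^2)
  zr <- pi * w0^2 / lam
  wz <- w0 * sqrt(1 + (zd / zr)^2)
  int1 <- rowSums(abs(u2)^2)
  m2 <- sum(xv^2 * int1) / sum(int1)
  expect_equal(2 * sqrt(m2), wz, tolerance = 0.01)
})

test_that("the lenslet phase mask is phase-only, tiled, and a thin lens per tile", {
  g <- geom_micro()
  f0 <- pupil_field(rep(0, 44), g)
  fm <- propagate_to_mla(f0)
  fb <- apply_mla(fm)
  inside <- abs(fb$u) > 0
  expect_equal(abs(fb$u)[inside], abs(fm$u)[inside], tolerance = 1e-12)
  # tile periodicity: the 1-d phase repeats every lenslet pitch
  spl <- g$lenslet_pitch / fb$pitch
  n <- nrow(fb$u)
  xv <- shwfsr:::field_coords(n, fb$pitch)
  half <- g$aperture_side / 2
  core <- which(abs(xv) < half - g$lenslet_pitch)
  xl <- ((xv + half) %% g$lenslet_pitch) - g$lenslet_pitch / 2
  ph <- -pi * xl^2 / (g$wavelength * g$focal_length)
  expect_equal(ph[core], ph[core + spl], tolerance = 1e-9)
  # single-lenslet geometry: the mask is one thin lens
  g1 <- shwfs_geometry(pupil_diameter_mm = 0.3, lenslet_count = 1,
                       lenslet_pitch_um = 300, pixel_pitch_um = 300 / 46)
  f1 <- apply_mla(propagate_to_mla(pupil_field(rep(0, 44), g1)))
  n1 <- nrow(f1$u)
  x1 <- shwfsr:::field_coords(n1, f1$pitch)
  # pick a point inside the pupil disk, off the lenslet axis
  iy <- which.min(abs(x1 - 0.3 * g1$pupil_diameter / 2))
  ix <- which.min(abs(x1 + 0.2 * g1$pupil_diameter / 2))
  expected <- exp(complex(imaginary = -pi * (x1[iy]^2 + x1[ix]^2) /
                            (g1$wavelength * g1$focal_length)))
  expect_equal(f1$u[iy, ix], expected, tolerance = 1e-9)
  expect_error(apply_mla(f0), "MLA front")
  expect_error(propagate_to_sensor(fm), "MLA back")
})

test_that("detector binning conserves energy and intensities are nonnegative", {
  x <- matrix(runif(36), 6)
  b <- shwfsr:::bin_matrix(x, 2)
  expect_equal(sum(b), sum(x), tolerance = 1e-12)
  expect_equal(dim(b), c(3, 3))
  expect_equal(b[1, 1], sum(x[1:2, 1:2]))
  h <- render_cached("micro_zero", rep(0, 44), geom_micro())
  expect_true(all(h$intensity >= 0))
  expect_gt(h$energy_kept, 0.99)
})

test_that("zero aberration yields one centered spot per interior sub-aperture", {
  g <- geom_micro_sq()
  h <- render_cached("micro_sq_zero", rep(0, 44), g)
  cent <- measure_centroids(h)
  ring <- cell_ring(cent, g)
  expect_equal(sum(cent$valid), 64)
  err <- sqrt(cent$dx_px^2 + cent$dy_px^2)
  expect_lt(max(err[ring >= 2]), 0.05)
})

test_that("pure tilt displaces every spot by f lambda grad W, and shifts the image", {
  g <- geom_micro_sq()
  a <- 0.5
  h <- render_cached("micro_sq_tiltx", unit_coeffs(2, a), g)
  cent <- measure_centroids(h)
  ring <- cell_ring(cent, g)
  expected <- g$focal_length * g$wavelength * 2 * a /
    (g$pupil_diameter / 2) / g$pixel_pitch
  k <- ring >= 2
  expect_lt(max(abs(cent$dx_px[k] - expected)), 0.1)
  expect_lt(max(abs(cent$dy_px[k])), 0.1)
  # shift theorem: adding tilt to an aberrated image translates it
  base <- unit_coeffs(4, 0.3) + unit_coeffs(6, 0.1)
  h0 <- render_hartmannogram(base, g)
  h1 <- render_hartmannogram(base + unit_coeffs(2, a), g)
  com <- function(m) {
    tot <- sum(m)
    c(sum(colSums(m) * (seq_len(ncol(m)) - 1)),
      sum(rowSums(m) * (seq_len(nrow(m)) - 1))) / tot
  }
  shift <- com(h1$intensity) - com(h0$intensity)
  expect_equal(shift[1], expected, tolerance = 0.1)
  expect_equal(shift[2], 0, tolerance = 0.1)
})

test_that("defocus displacement is radial, linear in amplitude, and matches the ray oracle", {
  g <- geom_micro()
  o1 <- spot_displacement_oracle(unit_coeffs(4), g)
  # oracle linearity in amplitude
  o2 <- spot_displacement_oracle(unit_coeffs(4, 2), g)
  expect_equal(o2$dx_px, 2 * o1$dx_px, tolerance = 1e-12)
  h <- render_cached("micro_defoc1", unit_coeffs(4), g)
  cent <- measure_centroids(h)
  k <- cent$in_pupil & cent$valid & cent$inside_frac > 0.999
  derr <- sqrt((cent$dx_px - o1$dx_px)^2 + (cent$dy_px - o1$dy_px)^2)[k]
  dmag <- sqrt(o1$dx_px^2 + o1$dy_px^2)[k]
  expect_lt(max(derr / dmag), 0.05)
  # measured displacement linear in a4 across amplitudes (corner cells)
  amps <- c(0.5, 1, 1.5)
  cell <- which(k)[which.max(dmag)]
  disp <- vapply(amps, function(a) {
    hh <- render_hartmannogram(unit_coeffs(4, a), g)
    cc <- measure_centroids(hh)
    sqrt(cc$dx_px[cell]^2 + cc$dy_px[cell]^2)
  }, numeric(1))
  fit <- stats::lm(disp ~ amps)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("large defocus drives spots out of home cells and breaks the modal fit", {
  g <- geom_micro()
  big <- unit_coeffs(4, 6)  # far beyond the half-pitch critical amplitude
  o <- spot_displacement_oracle(big, g)
  expect_gt(max(sqrt(o$dx_px^2 + o$dy_px^2)[o$in_pupil]),
            g$pixels_per_subaperture / 2)
  h <- render_hartmannogram(big, g)
  # outermost spots also leave the detector entirely
  expect_lt(h$energy_kept, 0.99)
  # the abnormal regime: the classical pipeline exceeds the protocol
  # threshold by a wide margin
  est <- reconstruct_modal(h, mm_micro())
  expect_gt(residual_rms(big, est), 0.0894)
})

test_that("bicubic downsampling preserves constants and spot geometry", {
  expect_equal(downsample_hartmannogram(matrix(3, 40, 40), 17, normalize = FALSE),
               matrix(3, 17, 17), tolerance = 1e-9)
  g <- geom_micro()
  h <- render_cached("micro_tilt_ds", unit_coeffs(2, 0.4), g)
  full <- h$intensity
  ds <- downsample_hartmannogram(h, 64)
  expect_equal(max(ds), 1)
  com <- function(m) {
    tot <- sum(m)
    c(sum(colSums(m) * (seq_len(ncol(m)) - 1)),
      sum(rowSums(m) * (seq_len(nrow(m)) - 1))) / tot
  }
  expect_equal(com(ds), (com(full) + 0.5) / 2 - 0.5, tolerance = 0.5)
  expect_error(downsample_hartmannogram(h, 0), "positive")
  expect_error(downsample_hartmannogram(h, 500), "exceeds")
})

test_that("the Nyquist guard escalates sampling instead of aliasing", {
  g <- geom_micro()
  steep <- unit_coeffs(4, 15)
  expect_error(pupil_field(steep, g, oversample = 1, auto_oversample = FALSE),
               "Nyquist")
  f <- pupil_field(steep, g, oversample = 1, auto_oversample = TRUE)
  expect_gt(f$oversample, 1)
})
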