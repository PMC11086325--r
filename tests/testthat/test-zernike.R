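# Zernike machinery: indexing, normalization, gradients, synthesis.

test_that("OSA index round-trips and matches the (n ascending, m ascending) enumeration", {
  # independent enumeration oracle
  enum <- do.call(rbind, lapply(0:8, function(n) {
    m <- seq(-n, n, by = 2)
    data.frame(n = n, m = m)
  }))
  enum$j <- seq_len(nrow(enum)) - 1
  got <- osa_to_nm(enum$j)
  expect_equal(got$n, enum$n)
  expect_equal(got$m, enum$m)
  expect_equal(nm_to_osa(got$n, got$m), enum$j)
  # named examples: defocus, piston, last mode of order 8
  expect_equal(unlist(osa_to_nm(4)[, c("n", "m")], use.names = FALSE), c(2, 0))
  expect_equal(unlist(osa_to_nm(0)[, c("n", "m")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(osa_to_nm(44)[, c("n", "m")], use.names = FALSE), c(8, 8))
  # modes 1..44 cover radial orders 1..8 exactly
  tab <- osa_to_nm(1:44)
  expect_setequal(unique(tab$n), 1:8)
  expect_error(osa_to_nm(-1), "non-negative")
  expect_error(osa_to_nm(2.5), "integer")
  expect_error(nm_to_osa(3, 2), "invalid")
})

test_that("mode evaluation matches the radial-polynomial closed forms", {
  expect_equal(zernike_eval(3, 0, 0.7), 0)                 # rho^2 factor
  expect_equal(zernike_eval(4, 1 / sqrt(2), 1.3), 0, tolerance = 1e-12)
  expect_equal(zernike_eval(5, 1, 0), sqrt(6))             # sqrt6 rho^2 cos2t
  expect_equal(zernike_eval(4, 0, 0), -sqrt(3))            # sqrt3 (2rho^2-1)
  # oracle: explicit radial sum formula for a handful of modes/points
  radial <- function(n, m, rho) {
    s <- 0:((n - m) / 2)
    sum((-1)^s * factorial(n - s) /
          (factorial(s) * factorial((n + m) / 2 - s) *
             factorial((n - m) / 2 - s)) * rho^(n - 2 * s))
  }
  set.seed(4)
  for (j in c(6, 12, 20, 31, 44)) {
    nm <- osa_to_nm(j)
    norm <- sqrt(2 * (nm$n + 1) / (1 + (nm$m == 0)))
    trig <- if (nm$m >= 0) function(t) cos(nm$m * t) else function(t) sin(-nm$m * t)
    for (i in 1:5) {
      rho <- runif(1); th <- runif(1, 0, 2 * pi)
      expect_equal(zernike_eval(j, rho, th),
                   norm * radial(nm$n, abs(nm$m), rho) * trig(th),
                   tolerance = 1e-10)
    }
  }
  expect_error(zernike_eval(4, 1.2, 0), "rho")
})

test_that("basis is orthonormal on the disk", {
  g <- pupil_grid(512)
  m <- g$mask
  z <- vapply(1:44, function(j) {
    shwfsr:::poly_eval_grid(shwfsr:::zernike_xy_poly(j), g$x, g$y)[m]
  }, numeric(sum(m)))
  gram <- crossprod(z) / sum(m)
  expect_lt(max(abs(gram - diag(44))), 2e-3)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(11)
  h <- 1e-5
  for (trial in 1:100) {
    j <- sample(1:44, 1)
    rho <- runif(1, 0.05, 0.95)
    th <- runif(1, 0, 2 * pi)
    x <- rho * cos(th); y <- rho * sin(th)
    gr <- zernike_gradient(j, rho, th)
    p <- function(xx, yy) zernike_eval(j, sqrt(xx^2 + yy^2), atan2(yy, xx))
    fdx <- (p(x + h, y) - p(x - h, y)) / (2 * h)
    fdy <- (p(x, y + h) - p(x, y - h)) / (2 * h)
    expect_equal(gr$dx, fdx, tolerance = 1e-6)
    expect_equal(gr$dy, fdy, tolerance = 1e-6)
  }
  expect_equal(unlist(zernike_gradient(4, 0, 0)), c(dx = 0, dy = 0))
  # tilt gradient is constant over the disk
  g1 <- zernike_gradient(1, 0.2, 0.4)
  g2 <- zernike_gradient(1, 0.9, 2.1)
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("wavefront synthesis, RMS and projection are mutually consistent", {
  g <- pupil_grid(512)
  expect_equal(max(abs(wavefront_from_coeffs(rep(0, 44), g)$values), na.rm = TRUE), 0)
  # single mode equals pointwise evaluation; superposition is additive
  w4 <- wavefront_from_coeffs(unit_coeffs(4), g)
  iy <- 300; ix <- 180
  rho <- sqrt(g$x[ix]^2 + g$y[iy]^2)
  expect_equal(w4$values[iy, ix],
               zernike_eval(4, rho, atan2(g$y[iy], g$x[ix])), tolerance = 1e-12)
  mix <- wavefront_from_coeffs(0.5 * unit_coeffs(3) + 0.5 * unit_coeffs(4), g)
  w3 <- wavefront_from_coeffs(unit_coeffs(3), g)
  expect_equal(mix$values, 0.5 * w3$values + 0.5 * w4$values, tolerance = 1e-12)
  # rms identities
  expect_equal(wavefront_rms(unit_coeffs(4)), 1)
  expect_equal(wavefront_rms(c(2, 0, 0, 1, rep(0, 40)), exclude = c(1, 2)), 1)
  set.seed(7)
  a <- rnorm(44, sd = 0.3)
  wf <- wavefront_from_coeffs(a, g)
  grid_rms <- sqrt(mean((wf$values[g$mask] - mean(wf$values[g$mask]))^2))
  expect_equal(wavefront_rms(a), grid_rms, tolerance = 1e-3)
  # mask-weighted projection recovers the coefficients (finer grid: the
  # discretized inner products converge at second order)
  wf2 <- wavefront_from_coeffs(a, pupil_grid(1024))
  proj <- project_wavefront(wf2, 1:44)
  expect_lt(max(abs(proj - a)), 1e-3)
  expect_error(wavefront_rms(a, exclude = 45), "subset")
})
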