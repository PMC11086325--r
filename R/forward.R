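# Physical-optics forward model: wavefront -> complex pupil field ->
# Fresnel propagation to the lenslet array -> tiled thin-lens phase ->
# Fresnel propagation to the detector -> intensity raster (Hartmannogram).
#
# Propagation uses the transfer-function (angular-spectrum) form of the
# Fresnel operator, which preserves the sample pitch and is exactly unitary;
# its sampling condition lambda*f/L < pitch holds for every shipped geometry
# at the default 2x oversampling. The lenslet array is modeled as a tiled
# per-lenslet thin-lens phase over the square MLA aperture (opaque outside).
# Wraparound energy is suppressed by zero-padding the propagation window
# beyond the detector and cropping afterwards; the cropped energy fraction is
# recorded on the result.

field_freqs <- function(n, pitch) {
  (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / (n * pitch)
}

#' Fresnel (angular-spectrum) propagation of a sampled complex field
#'
#' @param u Complex matrix (rows index y).
#' @param pitch Physical sample pitch (m).
#' @param wavelength Wavelength (m).
#' @param distance Propagation distance (m).
#' @return Complex matrix of the propagated field on the same grid.
#' @keywords internal
propagate_field <- function(u, pitch, wavelength, distance) {
  n <- nrow(u)
  stopifnot(ncol(u) == n)
  f <- field_freqs(n, pitch)
  ph <- -pi * wavelength * distance * outer(f^2, f^2, "+")
  h <- complex(modulus = 1, argument = ph)
  stats::fft(stats::fft(u) * h, inverse = TRUE) / length(u)
}

# Internal constructor for field objects moving through the chain.
new_field <- function(u, pitch, plane, geometry, oversample, n_det) {
  structure(list(u = u, pitch = pitch, plane = plane, geometry = geometry,
                 oversample = oversample, n_det = n_det),
            class = "shwfs_field")
}

field_coords <- function(n, pitch) (seq_len(n) - (n + 1) / 2) * pitch

#' Complex field at the sensor entrance pupil
#'
#' Builds `U0 = exp(i 2 pi W) * P(x, y)` on an oversampled grid spanning the
#' (zero-padded) lenslet-array aperture, with unit amplitude inside the pupil
#' disk and zero outside. A Nyquist guard checks the per-sample phase
#' increment of the aberrated field and, when it exceeds half a wave,
#' doubles the oversampling (up to `max_oversample`) rather than silently
#' aliasing.
#'
#' @param coeffs Zernike coefficient vector (waves), OSA modes `1..K`.
#' @param geometry A [shwfs_geometry()].
#' @param oversample Pupil samples per detector pixel side (integer `>= 1`).
#' @param pad_samples Zero-padding samples added on each side of the detector
#'   window (defaults to an estimate from the ray-optics spot displacement).
#' @param auto_oversample Escalate oversampling on a Nyquist-guard trip
#'   instead of erroring.
#' @param max_oversample Upper bound for the escalation.
#' @return A `shwfs_field` at plane `"aperture"`.
#' @export
pupil_field <- function(coeffs, geometry, oversample = 2, pad_samples = NULL,
                        auto_oversample = TRUE, max_oversample = 8) {
  stopifnot(inherits(geometry, "shwfs_geometry"))
  check_coeffs(coeffs)
  oversample <- as.integer(oversample)
  stopifnot(oversample >= 1)
  repeat {
    n_det <- geometry$detector_side_px * oversample
    pitch <- geometry$lenslet_pitch / (geometry$pixels_per_subaperture * oversample)
    if (is.null(pad_samples)) {
      pad_samples <- default_pad_samples(coeffs, geometry, pitch, n_det)
    }
    np <- padded_size(n_det, pad_samples)
    xv <- field_coords(np, pitch)
    r_pupil <- geometry$pupil_diameter / 2
    xn <- xv / r_pupil
    mask <- pupil_mask(xn, geometry)
    w <- poly_eval_grid(zernike_poly_combine(coeffs), xn, xn)
    # Nyquist guard: largest wavefront increment between adjacent in-mask
    # samples must stay below half a wave (pi of phase)
    winc <- max(masked_increment(w, mask), 0)
    if (winc > 0.5) {
      if (auto_oversample && oversample * 2 <= max_oversample) {
        oversample <- oversample * 2L
        pad_samples <- NULL
        next
      }
      stop(sprintf(paste0(
        "pupil sampling violates the Nyquist guard (max %.2f waves/sample); ",
        "increase `oversample`"), winc), call. = FALSE)
    }
    u <- matrix(0i, np, np)
    u[mask] <- complex(modulus = 1, argument = 2 * pi * w[mask])
    return(new_field(u, pitch, "aperture", geometry, oversample, n_det))
  }
}

masked_increment <- function(w, mask) {
  dx <- abs(w[, -1] - w[, -ncol(w)]); mx <- mask[, -1] & mask[, -ncol(w)]
  dy <- abs(w[-1, ] - w[-nrow(w), ]); my <- mask[-1, ] & mask[-nrow(w), ]
  max(c(dx[mx], dy[my], 0))
}

pupil_mask <- function(xn, geometry) {
  if (identical(geometry$pupil_shape, "square")) {
    half_n <- geometry$aperture_side / geometry$pupil_diameter
    inside <- abs(xn) <= half_n + 1e-12
    outer(inside, inside, "&")
  } else {
    outer(xn^2, xn^2, "+") <= 1
  }
}

default_pad_samples <- function(coeffs, geometry, pitch, n_det) {
  # ray-optics bound on spot displacement plus a diffraction margin
  disp <- 0
  if (any(coeffs != 0)) {
    v <- seq(-1, 1, length.out = 41)
    if (identical(geometry$pupil_shape, "square")) {
      v <- v * geometry$aperture_side / geometry$pupil_diameter
      keep <- matrix(TRUE, length(v), length(v))
    } else {
      keep <- outer(v^2, v^2, "+") <= 1
    }
    df <- zernike_poly_combine(coeffs)
    gx <- poly_eval_grid(poly_deriv(df, "x"), v, v)
    gy <- poly_eval_grid(poly_deriv(df, "y"), v, v)
    slope <- max(sqrt(gx[keep]^2 + gy[keep]^2)) / (geometry$pupil_diameter / 2)
    disp <- geometry$focal_length * geometry$wavelength * slope
  }
  margin <- 4 * geometry$wavelength * geometry$focal_length /
    geometry$lenslet_pitch + geometry$lenslet_pitch
  max(ceiling(n_det / 8), ceiling((disp + margin) / pitch))
}

padded_size <- function(n_det, pad_samples) {
  np <- stats::nextn(n_det + 2 * pad_samples, c(2, 3, 5))
  while (np %% 2 != n_det %% 2) np <- stats::nextn(np + 1, c(2, 3, 5))
  np
}

#' Propagate the aperture field to the front plane of the lenslet array
#'
#' Fresnel propagation over the geometry's aperture-to-MLA distance. With
#' the default pupil-conjugate layout (distance 0) this is a relabeling;
#' with a nonzero distance it is a genuine diffraction step.
#'
#' @param field A `shwfs_field` at plane `"aperture"`.
#' @return A `shwfs_field` at plane `"mla_front"`.
#' @export
propagate_to_mla <- function(field) {
  stopifnot(inherits(field, "shwfs_field"))
  if (field$plane != "aperture") stop("field is not at the aperture plane", call. = FALSE)
  g <- field$geometry
  u <- if (g$aperture_to_mla > 0) {
    propagate_field(field$u, field$pitch, g$wavelength, g$aperture_to_mla)
  } else {
    field$u
  }
  new_field(u, field$pitch, "mla_front", g, field$oversample, field$n_det)
}

#' Apply the lenslet-array phase mask
#'
#' Multiplies the field by the tiled per-lenslet thin-lens phase
#' `exp(-i k r_loc^2 / (2 f))`, with `r_loc` measured from each lenslet
#' center; the array aperture is opaque outside the MLA square. The grid must
#' tile each lenslet with an integer number of samples.
#'
#' @param field A `shwfs_field` at plane `"mla_front"`.
#' @return A `shwfs_field` at plane `"mla_back"`.
#' @export
apply_mla <- function(field) {
  stopifnot(inherits(field, "shwfs_field"))
  if (field$plane != "mla_front") stop("field is not at the MLA front plane", call. = FALSE)
  g <- field$geometry
  spl <- g$lenslet_pitch / field$pitch
  if (abs(spl - round(spl)) > 1e-9) {
    stop("field grid does not tile the lenslet pitch with integer samples",
         call. = FALSE)
  }
  n <- nrow(field$u)
  xv <- field_coords(n, field$pitch)
  half <- g$aperture_side / 2
  inside <- abs(xv) < half - 1e-12
  # local coordinate within each lenslet tile
  xl <- ((xv + half) %% g$lenslet_pitch) - g$lenslet_pitch / 2
  xl[!inside] <- NA
  phase1d <- -pi * xl^2 / (g$wavelength * g$focal_length)
  ph <- outer(phase1d, phase1d, "+")
  m <- matrix(complex(real = 0), n, n)
  ok <- !is.na(ph)
  m[ok] <- complex(modulus = 1, argument = ph[ok])
  new_field(field$u * m, field$pitch, "mla_back", g, field$oversample, field$n_det)
}

#' Propagate to the detector and record the Hartmannogram
#'
#' Fresnel propagation over one focal length, squared modulus, central crop
#' to the detector window and block-binning from the oversampled grid to
#' detector pixels. All lenslet contributions live in one coherent field, so
#' interference between neighbouring spots is captured.
#'
#' @param field A `shwfs_field` at plane `"mla_back"`.
#' @return A `hartmannogram` object: nonnegative intensity matrix
#'   (`detector_side_px` square, rows index y), the geometry, and energy
#'   diagnostics (`energy_kept` = fraction within the detector window).
#' @export
propagate_to_sensor <- function(field) {
  stopifnot(inherits(field, "shwfs_field"))
  if (field$plane != "mla_back") stop("field is not at the MLA back plane", call. = FALSE)
  g <- field$geometry
  u <- propagate_field(field$u, field$pitch, g$wavelength, g$focal_length)
  ii <- Re(u * Conj(u))
  np <- nrow(ii)
  off <- (np - field$n_det) / 2
  crop <- ii[(off + 1):(off + field$n_det), (off + 1):(off + field$n_det)]
  total <- sum(ii)
  os <- field$oversample
  raster <- bin_matrix(crop, os)
  new_hartmannogram(raster, g,
                    energy_kept = if (total > 0) sum(crop) / total else 1,
                    oversample = os)
}

bin_matrix <- function(x, f) {
  if (f == 1) return(x)
  n <- nrow(x) / f
  dim(x) <- c(f, n, f, n)
  colSums(colSums(aperm(x, c(1, 3, 2, 4))))
}

new_hartmannogram <- function(intensity, geometry, coeffs = NULL,
                              energy_kept = NA_real_, oversample = NA_integer_) {
  structure(list(intensity = intensity, geometry = geometry, coeffs = coeffs,
                 energy_kept = energy_kept, oversample = oversample),
            class = "hartmannogram")
}

#' @export
print.hartmannogram <- function(x, ...) {
  cat(sprintf(
    "<hartmannogram> %d x %d px, %dx%d lenslets, energy kept %.4f\n",
    nrow(x$intensity), ncol(x$intensity), x$geometry$lenslet_count,
    x$geometry$lenslet_count, x$energy_kept))
  invisible(x)
}

#' Render a Hartmannogram from Zernike coefficients
#'
#' Full forward chain: pupil field, Fresnel propagation to the lenslet
#' array, tiled lens phase, Fresnel propagation to the detector, intensity,
#' binning; optional photon/read noise applied last. Deterministic given
#' `seed` when noise is on.
#'
#' @inheritParams pupil_field
#' @param noise Optional list with `photons` (expected photon count over the
#'   raster; Poisson shot noise) and/or `read_noise_sd` (Gaussian, photon
#'   units). `NULL` (default) renders noiselessly.
#' @param seed RNG seed for the noise draw.
#' @return A `hartmannogram` carrying the generating coefficients as label.
#' @examples
#' g <- shwfs_geometry_profile("micro")
#' h <- render_hartmannogram(c(0, 0, 0, 1), g)
#' @export
render_hartmannogram <- function(coeffs, geometry, oversample = 2,
                                 pad_samples = NULL, noise = NULL,
                                 seed = NULL, auto_oversample = TRUE,
                                 max_oversample = 8) {
  f0 <- pupil_field(coeffs, geometry, oversample, pad_samples,
                    auto_oversample, max_oversample)
  h <- propagate_to_sensor(apply_mla(propagate_to_mla(f0)))
  h$coeffs <- coeffs
  if (!is.null(noise)) h <- apply_sensor_noise(h, noise, seed)
  h
}

apply_sensor_noise <- function(h, noise, seed = NULL) {
  ras <- h$intensity
  draw <- function() {
    if (!is.null(noise$photons)) {
      scale <- noise$photons / max(sum(ras), .Machine$double.eps)
      ras <- matrix(stats::rpois(length(ras), ras * scale), nrow(ras)) / scale
    }
    if (!is.null(noise$read_noise_sd) && noise$read_noise_sd > 0) {
      ras <- ras + stats::rnorm(length(ras), 0, noise$read_noise_sd)
    }
    pmax(ras, 0)
  }
  h$intensity <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  h
}

#' Downsample a Hartmannogram raster
#'
#' Bicubic (Catmull-Rom) interpolation to `target_side` pixels per side,
#' clamped to nonnegative values and, by default, normalized to `[0, 1]` by
#' the per-image maximum — the same normalization the network sees at
#' training time.
#'
#' @param h A `hartmannogram` or a plain intensity matrix.
#' @param target_side Output side length (`<=` input side).
#' @param normalize Divide by the per-image maximum (default `TRUE`).
#' @return Numeric matrix `target_side` square.
#' @export
downsample_hartmannogram <- function(h, target_side, normalize = TRUE) {
  x <- if (inherits(h, "hartmannogram")) h$intensity else h
  target_side <- as.integer(target_side)
  if (target_side <= 0) stop("target_side must be positive", call. = FALSE)
  if (target_side > nrow(x)) stop("target_side exceeds the raster side", call. = FALSE)
  y <- pmax(bicubic_resize(x, target_side, target_side), 0)
  if (normalize && max(y) > 0) y <- y / max(y)
  y
}

# Sub-aperture-averaged Zernike gradients in normalized pupil units; shared
# by the ray-displacement oracle and the modal reconstruction matrix.
# Coefficient-independent, so memoized per (geometry, modes, subgrid).
.gradient_cache <- new.env(parent = emptyenv())

cell_mean_gradients <- function(geometry, modes = 1:44, subgrid = 11) {
  key <- paste(c(unlist(geometry[c("pupil_diameter", "lenslet_count",
                                   "lenslet_pitch", "pupil_shape")]),
                 modes, subgrid), collapse = "|")
  hit <- .gradient_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- cell_mean_gradients_impl(geometry, modes, subgrid)
  .gradient_cache[[key]] <- out
  out
}

cell_mean_gradients_impl <- function(geometry, modes = 1:44, subgrid = 11) {
  cells <- subaperture_table(geometry, subgrid)
  r_pupil <- geometry$pupil_diameter / 2
  off <- (seq_len(subgrid) - (subgrid + 1) / 2) / subgrid *
    (geometry$lenslet_pitch / r_pupil)
  gx <- matrix(0, nrow(cells), length(modes))
  gy <- matrix(0, nrow(cells), length(modes))
  dpoly <- lapply(modes, function(j) {
    df <- zernike_xy_poly(j)
    list(dx = poly_deriv(df, "x"), dy = poly_deriv(df, "y"))
  })
  square <- identical(geometry$pupil_shape, "square")
  for (i in seq_len(nrow(cells))) {
    px <- rep(cells$ux[i] + off, times = subgrid)
    py <- rep(cells$uy[i] + off, each = subgrid)
    keep <- if (square) rep(TRUE, length(px)) else px^2 + py^2 <= 1
    if (!any(keep)) next
    px <- px[keep]; py <- py[keep]
    for (k in seq_along(modes)) {
      gx[i, k] <- mean(poly_eval_points(dpoly[[k]]$dx, px, py))
      gy[i, k] <- mean(poly_eval_points(dpoly[[k]]$dy, px, py))
    }
  }
  list(cells = cells, gx = gx, gy = gy, modes = modes)
}

#' Ray-optics spot displacement oracle
#'
#' Paraxial prediction of each spot's centroid displacement: the
#' sub-aperture-averaged wavefront gradient maps to a displacement
#' `f * lambda * grad W` on the detector. Used as the independent check of
#' the diffraction simulation and of the classical slope conversion.
#'
#' @param coeffs Zernike coefficients in waves.
#' @param geometry A [shwfs_geometry()].
#' @param subgrid Per-cell gradient averaging grid.
#' @return [subaperture_table()] tibble plus predicted `dx_px`, `dy_px`.
#' @export
spot_displacement_oracle <- function(coeffs, geometry, subgrid = 11) {
  check_coeffs(coeffs)
  cg <- cell_mean_gradients(geometry, seq_along(coeffs), subgrid)
  r_pupil <- geometry$pupil_diameter / 2
  scale <- geometry$focal_length * geometry$wavelength /
    (r_pupil * geometry$pixel_pitch)
  out <- cg$cells
  out$dx_px <- as.numeric(cg$gx %*% coeffs) * scale
  out$dy_px <- as.numeric(cg$gy %*% coeffs) * scale
  out
}
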