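# Classical Shack-Hartmann reconstruction: thresholded center-of-mass
# centroiding per sub-aperture, conversion of centroid displacements to
# wavefront slopes, and least-squares modal fitting of Zernike coefficients
# through the sub-aperture-averaged gradient matrix.

#' Measure spot centroids per sub-aperture
#'
#' Background-thresholded center of mass inside each lenslet's detector
#' cell: `threshold_fraction` of the cell maximum is subtracted, negatives
#' clamped to zero, and the centroid computed on what remains. A cell is
#' flagged invalid when its post-threshold energy falls below
#' `min_energy_frac` of the mean post-threshold cell energy (spotless cell).
#'
#' @param h A `hartmannogram`.
#' @param threshold_fraction Fraction of the per-cell maximum subtracted as
#'   background (in `[0, 1)`, default 0.1).
#' @param min_energy_frac Validity floor relative to the mean cell energy
#'   (default 0.01).
#' @return The [subaperture_table()] tibble plus measured `cx`, `cy`
#'   (0-based detector px), displacements `dx_px`, `dy_px` from the cell
#'   center, cell `energy`, and `valid`.
#' @export
measure_centroids <- function(h, threshold_fraction = 0.1,
                              min_energy_frac = 0.01) {
  stopifnot(inherits(h, "hartmannogram"))
  if (threshold_fraction < 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie in [0, 1)", call. = FALSE)
  }
  g <- h$geometry
  ras <- h$intensity
  if (nrow(ras) != g$detector_side_px) {
    stop("raster size does not match the geometry", call. = FALSE)
  }
  ppsa <- g$pixels_per_subaperture
  cells <- subaperture_table(g)
  n <- nrow(cells)
  cx <- cy <- en <- numeric(n)
  for (i in seq_len(n)) {
    rows <- cells$row[i] * ppsa + seq_len(ppsa)   # detector y
    cols <- cells$col[i] * ppsa + seq_len(ppsa)   # detector x
    sub <- ras[rows, cols]
    sub <- pmax(sub - threshold_fraction * max(sub), 0)
    en[i] <- sum(sub)
    if (en[i] > 0) {
      px <- cols - 1  # 0-based pixel centers
      py <- rows - 1
      cx[i] <- sum(colSums(sub) * px) / en[i]
      cy[i] <- sum(rowSums(sub) * py) / en[i]
    } else {
      cx[i] <- cy[i] <- NA_real_
    }
  }
  floor_e <- min_energy_frac * mean(en)
  cells$cx <- cx
  cells$cy <- cy
  cells$dx_px <- cx - cells$cx_px
  cells$dy_px <- cy - cells$cy_px
  cells$energy <- en
  cells$valid <- en > floor_e & is.finite(cx)
  cells
}

#' Convert centroid displacements to wavefront slopes
#'
#' The paraxial spot displacement is `f * lambda * grad W` (W in waves), so
#' the slope in normalized pupil units (waves per unit pupil radius, the
#' units of [zernike_gradient()]) is
#' `s = d_px * pixel_pitch * R_pupil / (f * lambda)`.
#'
#' @param centroids Output of [measure_centroids()].
#' @param geometry The matching [shwfs_geometry()].
#' @return The input tibble plus `sx`, `sy` slope columns.
#' @export
slopes_from_centroids <- function(centroids, geometry) {
  scale <- geometry$pixel_pitch * (geometry$pupil_diameter / 2) /
    (geometry$focal_length * geometry$wavelength)
  centroids$sx <- centroids$dx_px * scale
  centroids$sy <- centroids$dy_px * scale
  centroids
}

#' Build the modal reconstruction matrix
#'
#' Rows are the x-slopes then y-slopes of the in-pupil cells; columns are
#' Zernike modes; entries are the analytic mode gradients averaged over each
#' cell's footprint inside the unit disk (fine sub-grid). The condition
#' number is attached; a rank-deficient system warns.
#'
#' @param geometry A [shwfs_geometry()].
#' @param modes Fitted OSA modes (default `1:44`).
#' @param subgrid Per-cell averaging grid (default 11).
#' @return A `modal_matrix` object: the matrix plus the cell table.
#' @export
build_modal_matrix <- function(geometry, modes = 1:44, subgrid = 11) {
  cg <- cell_mean_gradients(geometry, modes, subgrid)
  keep <- cg$cells$in_pupil
  if (!any(keep)) stop("no in-pupil sub-apertures", call. = FALSE)
  if (length(modes) > 2 * sum(keep)) {
    stop("more modes than slope measurements", call. = FALSE)
  }
  a <- rbind(cg$gx[keep, , drop = FALSE], cg$gy[keep, , drop = FALSE])
  sv <- svd(a, nu = 0, nv = 0)$d
  kappa <- sv[1] / sv[length(sv)]
  if (!is.finite(kappa) || sv[length(sv)] < 1e-10 * sv[1]) {
    warning(sprintf("modal matrix is rank deficient (condition number %.3g)",
                    kappa))
  }
  structure(list(matrix = a, cells = cg$cells[keep, ], modes = modes,
                 condition = kappa, geometry = geometry),
            class = "modal_matrix")
}

#' Least-squares modal reconstruction from measured slopes
#'
#' Solves the overdetermined slope system for the Zernike coefficients using
#' only cells that are both in the pupil and valid; piston is unrecoverable
#' and fixed at zero. When fewer than `min_valid_frac` of the in-pupil cells
#' are valid the result is returned flagged low-confidence (attribute
#' `low_confidence`) rather than erroring — a failing sensor still produces
#' an (incorrect) reconstruction, which the dynamic-range protocol must be
#' able to observe.
#'
#' @param slopes Output of [slopes_from_centroids()].
#' @param mmat A [build_modal_matrix()] for the same geometry.
#' @param min_valid_frac Validity fraction below which the result is flagged
#'   (default 0.5).
#' @return Coefficient vector over `mmat$modes` (waves), with attributes
#'   `low_confidence` and `n_valid`.
#' @export
modal_reconstruct <- function(slopes, mmat, min_valid_frac = 0.5) {
  stopifnot(inherits(mmat, "modal_matrix"))
  key <- paste(mmat$cells$row, mmat$cells$col)
  skey <- paste(slopes$row, slopes$col)
  idx <- match(key, skey)
  if (any(is.na(idx))) stop("slope table does not cover the modal cells", call. = FALSE)
  ok <- slopes$valid[idx] & is.finite(slopes$sx[idx]) & is.finite(slopes$sy[idx])
  nc <- nrow(mmat$cells)
  a <- mmat$matrix[c(which(ok), nc + which(ok)), , drop = FALSE]
  b <- c(slopes$sx[idx][ok], slopes$sy[idx][ok])
  coefs <- rep(0, length(mmat$modes))
  if (length(b) >= 1) {
    fit <- tryCatch(qr.solve(a, b, tol = 1e-10),
                    error = function(e) {
                      sv <- svd(a)
                      d <- ifelse(sv$d > 1e-10 * sv$d[1], 1 / sv$d, 0)
                      sv$v %*% (d * (t(sv$u) %*% b))
                    })
    coefs <- as.numeric(fit)
  }
  names(coefs) <- paste0("Z", mmat$modes)
  attr(coefs, "n_valid") <- sum(ok)
  attr(coefs, "low_confidence") <- sum(ok) < min_valid_frac * nc
  coefs
}

#' One-call modal pipeline
#'
#' Centroid, convert to slopes, and fit: the classical reconstruction of a
#' Hartmannogram.
#'
#' @param h A `hartmannogram`.
#' @param mmat Optional precomputed [build_modal_matrix()] (built on the fly
#'   otherwise).
#' @inheritParams measure_centroids
#' @inheritParams modal_reconstruct
#' @return Coefficient vector as in [modal_reconstruct()].
#' @export
reconstruct_modal <- function(h, mmat = NULL, threshold_fraction = 0.1,
                              min_energy_frac = 0.01, min_valid_frac = 0.5) {
  if (is.null(mmat)) mmat <- build_modal_matrix(h$geometry)
  cent <- measure_centroids(h, threshold_fraction, min_energy_frac)
  sl <- slopes_from_centroids(cent, h$geometry)
  modal_reconstruct(sl, mmat, min_valid_frac)
}

#' Residual wavefront RMS between true and estimated coefficients
#'
#' By orthonormality the residual-wavefront RMS is the Euclidean norm of the
#' coefficient error. Tilt/tip are excluded by default, matching the
#' convention for quoting ocular reconstruction accuracy.
#'
#' @param true,est Coefficient vectors (waves), or matrices with one sample
#'   per row.
#' @param exclude_tilt Drop OSA modes 1-2 from the sum (default `TRUE`).
#' @return Residual RMS in waves (vector, one value per sample).
#' @export
residual_rms <- function(true, est, exclude_tilt = TRUE) {
  if (is.vector(true)) true <- matrix(true, 1)
  if (is.vector(est)) est <- matrix(est, 1)
  stopifnot(ncol(true) == ncol(est), nrow(true) == nrow(est))
  d <- true - est
  if (exclude_tilt) d <- d[, -(1:2), drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Batch residual summary
#'
#' @inheritParams residual_rms
#' @param sd_type `"population"` (default, divisor `n`) or `"sample"`
#'   (divisor `n - 1`).
#' @return Tibble with `n`, `rmse_mean`, `rmse_sd`.
#' @export
residual_summary <- function(true, est, exclude_tilt = TRUE,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  r <- residual_rms(true, est, exclude_tilt)
  n <- length(r)
  s <- if (sd_type == "population") {
    sqrt(mean((r - mean(r))^2))
  } else {
    stats::sd(r)
  }
  tibble::tibble(n = n, rmse_mean = mean(r), rmse_sd = s)
}
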