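# Kolmogorov-turbulence Zernike statistics: the classical closed-form
# inter-mode covariance (gamma-function expression, scaled by
# (D/r0)^{5/3}), used here as an out-of-distribution generator for the
# generalization test of the learned reconstructor.

#' Turbulence model definition
#'
#' @param d_over_r0 Ratio of pupil diameter to Fried parameter (`> 0`).
#' @param n_modes Highest OSA mode generated (default 44).
#' @return A `turbulence_model` object.
#' @export
turbulence_model <- function(d_over_r0, n_modes = 44) {
  if (!is.finite(d_over_r0) || d_over_r0 <= 0) {
    stop("d_over_r0 must be positive", call. = FALSE)
  }
  structure(list(d_over_r0 = d_over_r0, n_modes = as.integer(n_modes)),
            class = "turbulence_model")
}

#' Kolmogorov Zernike covariance matrix
#'
#' Closed-form covariance of Noll-normalized Zernike coefficients under
#' Kolmogorov turbulence. Two modes covary only when they share the same
#' signed azimuthal frequency (same harmonic, same parity); every entry
#' scales as `(D/r0)^{5/3}`. Piston is excluded. The per-order variances
#' reproduce the classical tabulated constants (0.448, 0.0232, 0.0062, ...
#' rad^2 at `D/r0 = 1`).
#'
#' @param model A [turbulence_model()].
#' @param units `"waves"` (default; coefficients in waves) or `"radians"`
#'   (phase radians, the convention of the classical tables).
#' @return `n_modes x n_modes` covariance matrix over OSA modes `1..n_modes`.
#' @export
kolmogorov_covariance <- function(model, units = c("waves", "radians")) {
  stopifnot(inherits(model, "turbulence_model"))
  units <- match.arg(units)
  k <- model$n_modes
  tab <- osa_to_nm(1:k)
  cov <- matrix(0, k, k)
  for (i in 1:k) {
    for (j in i:k) {
      if (tab$m[i] != tab$m[j]) next
      v <- kolmogorov_cov_nm(tab$n[i], tab$n[j], abs(tab$m[i]))
      cov[i, j] <- v
      cov[j, i] <- v
    }
  }
  cov <- cov * model$d_over_r0^(5 / 3)
  if (units == "waves") cov <- cov / (2 * pi)^2
  cov
}

# covariance of Noll-normalized coefficients (rad^2) at D/r0 = 1 for radial
# orders n, n' sharing |m|
kolmogorov_cov_nm <- function(n, np, m) {
  0.0072 * pi^(8 / 3) * gamma(14 / 3) * sqrt((n + 1) * (np + 1)) *
    (-1)^((n + np - 2 * m) / 2) * gamma((n + np - 5 / 3) / 2) /
    (gamma((n - np + 17 / 3) / 2) * gamma((np - n + 17 / 3) / 2) *
       gamma((n + np + 23 / 3) / 2))
}

#' Sample Kolmogorov-turbulence Zernike coefficients
#'
#' White Gaussian draws transformed through an eigenfactorization of the
#' closed-form covariance (clipped to positive semidefinite). Tilt/tip can
#' be zeroed for tilt-removed statistics.
#'
#' @param model A [turbulence_model()].
#' @param n Number of samples.
#' @param seed Integer RNG seed (bit-for-bit determinism).
#' @param include_tilt Keep the tilt/tip modes (default `TRUE`).
#' @return `n x n_modes` matrix of coefficients in waves.
#' @export
sample_kolmogorov_coeffs <- function(model, n, seed = NULL, include_tilt = TRUE) {
  stopifnot(inherits(model, "turbulence_model"), n >= 0)
  k <- model$n_modes
  if (n == 0) return(matrix(numeric(0), 0, k))
  cov <- kolmogorov_covariance(model, units = "waves")
  if (!include_tilt && k >= 2) cov[1:2, ] <- cov[, 1:2] <- 0
  ev <- eigen(cov, symmetric = TRUE)
  factor <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  z <- seeded_normals(n, k, seed)
  z %*% t(factor)
}
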