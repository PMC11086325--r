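# Statistical generators of ocular aberration coefficients: a 44-mode
# multivariate-Gaussian population model (the standard description of
# human-eye Zernike statistics) and the order-proportion summary used to
# decide which modes matter for dynamic-range testing.

#' Construct an eye-population aberration model
#'
#' A multivariate Gaussian over the 44 non-piston OSA Zernike modes
#' (radial orders 1-8), coefficients in waves. The covariance must be
#' symmetric positive semidefinite (eigenvalues below `-1e-10` are rejected;
#' small negative eigenvalues are clipped to zero).
#'
#' @param mu Length-44 mean vector (waves).
#' @param sigma 44x44 covariance matrix (waves^2), or `NULL` with
#'   `sigma_diag` giving per-mode variances.
#' @param sigma_diag Optional length-44 vector of per-mode variances.
#' @return An `eye_model` object with elements `mu`, `sigma` and the
#'   factor used for sampling.
#' @export
eye_model <- function(mu, sigma = NULL, sigma_diag = NULL) {
  k <- length(mu)
  if (is.null(sigma)) {
    if (is.null(sigma_diag)) stop("supply `sigma` or `sigma_diag`", call. = FALSE)
    stopifnot(length(sigma_diag) == k, all(sigma_diag >= 0))
    sigma <- diag(sigma_diag, k)
  }
  stopifnot(is.matrix(sigma), nrow(sigma) == k, ncol(sigma) == k)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(1, max(abs(ev$values)))) {
    stop("covariance is not positive semidefinite", call. = FALSE)
  }
  vals <- pmax(ev$values, 0)
  factor <- ev$vectors %*% diag(sqrt(vals), k)
  structure(list(mu = as.numeric(mu), sigma = sigma, factor = factor, k = k),
            class = "eye_model")
}

#' Default stand-in eye-population model
#'
#' The published fits of clinical ocular Zernike statistics are not
#' reproducible from open sources, so the package ships a documented
#' stand-in with the qualitative structure of ocular populations: variance
#' concentrated in defocus and astigmatism and decaying steeply with radial
#' order, a slight myopic defocus bias, small tilt variability, and no
#' inter-mode correlation. Fully replaceable via [read_eye_model()].
#'
#' Per-mode standard deviations (waves at 840 nm): tilt/tip 0.2; astigmatism
#' (Z3, Z5) 1.0; defocus (Z4) 3.0; order 3 0.15; then 0.08, 0.04, 0.02,
#' 0.01, 0.005 for orders 4-8. Mean zero except defocus mean -0.5.
#'
#' @return An `eye_model`.
#' @export
default_eye_model <- function() {
  tab <- osa_to_nm(1:44)
  sd_order <- c(0.2, NA, 0.15, 0.08, 0.04, 0.02, 0.01, 0.005)
  s <- sd_order[tab$n]
  s[tab$j %in% c(3, 5)] <- 1.0
  s[tab$j == 4] <- 3.0
  mu <- rep(0, 44)
  mu[4] <- -0.5
  eye_model(mu, sigma_diag = s^2)
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf("<eye_model> %d modes; sd(Z4) = %.3g waves, total rms %.3g waves\n",
              x$k, sqrt(x$sigma[4, 4]), sqrt(sum(diag(x$sigma)))))
  invisible(x)
}

#' Sample aberration coefficient vectors from an eye model
#'
#' Independent draws from `N(mu, Sigma)`; bit-for-bit deterministic given
#' `seed`.
#'
#' @param model An [eye_model()].
#' @param n Number of samples (`>= 0`).
#' @param seed Integer RNG seed.
#' @return `n x 44` matrix, one coefficient vector (waves) per row.
#' @export
sample_eye_coeffs <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "eye_model"), n >= 0)
  if (n == 0) return(matrix(numeric(0), 0, model$k))
  z <- seeded_normals(n, model$k, seed)
  out <- z %*% t(model$factor)
  sweep(out, 2, model$mu, "+")
}

seeded_normals <- function(n, k, seed) {
  draw <- function() matrix(stats::rnorm(n * k), n, k)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Proportion of aberration power in the first K modes
#'
#' For each sample the squared coefficients are summed over modes `3..K`
#' and divided by the total over modes `3..44` (tilt/tip excluded on both
#' sides); the mean over samples is returned. Used to justify restricting
#' dynamic-range sweeps to the low-order modes.
#'
#' @param samples Matrix of coefficient vectors (rows = samples, 44 columns)
#'   or a single vector.
#' @param K Cutoff OSA index, `3 <= K <= 44`.
#' @return Mean proportion in `[0, 1]`.
#' @export
order_proportion <- function(samples, K) {
  if (is.vector(samples)) samples <- matrix(samples, 1)
  stopifnot(K >= 3, K <= ncol(samples), ncol(samples) >= 44 || K <= ncol(samples))
  hi <- 3:ncol(samples)
  tot <- rowSums(samples[, hi, drop = FALSE]^2)
  bad <- tot == 0
  if (any(bad)) {
    warning(sprintf("%d sample(s) with zero power in modes 3..%d excluded",
                    sum(bad), ncol(samples)))
    if (all(bad)) stop("no usable samples", call. = FALSE)
  }
  num <- rowSums(samples[, 3:K, drop = FALSE]^2)
  mean(num[!bad] / tot[!bad])
}

#' Read / write an eye model as a YAML config
#'
#' The file holds `mu` (44 numbers) and either `sigma_diag` (44 variances)
#' or `sigma` (44x44, row-major list of rows). Units are waves (squared
#' waves for the covariance).
#'
#' @param path File path.
#' @return An `eye_model` (for the reader); the writer returns `path`
#'   invisibly.
#' @export
read_eye_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("mu", "sigma_diag", "sigma"))
  if (length(unknown)) {
    stop("unknown eye-model keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  mu <- as.numeric(cfg$mu)
  if (!is.null(cfg$sigma)) {
    sig <- do.call(rbind, lapply(cfg$sigma, as.numeric))
    eye_model(mu, sigma = sig)
  } else {
    eye_model(mu, sigma_diag = as.numeric(cfg$sigma_diag))
  }
}

#' @rdname read_eye_model
#' @param model An [eye_model()] to serialize.
#' @export
write_eye_model <- function(model, path) {
  stopifnot(inherits(model, "eye_model"))
  yaml::write_yaml(list(
    mu = as.numeric(model$mu),
    sigma = lapply(seq_len(model$k), function(i) as.numeric(model$sigma[i, ]))),
    path)
  invisible(path)
}
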