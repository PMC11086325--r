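# Dynamic-range benchmarking protocol: sweep a single Zernike mode's
# amplitude against a pluggable reconstructor, locate the critical value at
# which the residual-wavefront RMS first exceeds the tolerance threshold
# (coarse scan + bisection to 1e-3 waves), and report the relative
# dynamic-range improvement between reconstructors.
#
# The default threshold is the literal protocol constant 0.0894 waves
# (the Marechal criterion 1/14 with a 25% tolerance, as printed).

#' Residual RMS of a single-mode aberration after reconstruction
#'
#' Renders a wavefront with `a_j = a` (all other modes zero), reconstructs
#' it with the supplied reconstructor, and returns the residual wavefront
#' RMS (tilt/tip excluded). A reconstructor error counts as total failure
#' (`Inf`, i.e. above any threshold).
#'
#' @param reconstructor Function `hartmannogram -> coefficient vector`.
#' @param j OSA mode index (3..44 in the protocol).
#' @param a Amplitude in waves (signed).
#' @param geometry A [shwfs_geometry()].
#' @param ... Passed to [render_hartmannogram()].
#' @return Residual RMS in waves.
#' @export
residual_for_amplitude <- function(reconstructor, j, a, geometry, ...) {
  stopifnot(is.function(reconstructor), j >= 1, j <= 44)
  coeffs <- rep(0, 44)
  coeffs[j] <- a
  h <- render_hartmannogram(coeffs, geometry, ...)
  est <- tryCatch(as.numeric(reconstructor(h)), error = function(e) NULL)
  if (is.null(est) || length(est) != 44 || any(!is.finite(est))) return(Inf)
  residual_rms(coeffs, est, exclude_tilt = TRUE)
}

#' Critical amplitude of a reconstructor for one mode
#'
#' Coarse scan outward from zero in signed `scan_step` increments until the
#' residual first exceeds `threshold` (first-crossing convention: the
#' dynamic range is the largest amplitude below which measurement is
#' continuously reliable), then bisection on the bracketing interval until
#' its width is at most `tol`. If the scan reaches `a_max` without a
#' failure the result is flagged unbounded at `a_max`.
#'
#' @param residual_fn Function `amplitude -> residual RMS` (see
#'   [residual_for_amplitude()] for the rendering version).
#' @param direction `+1` or `-1`.
#' @param threshold Residual-RMS tolerance in waves (default 0.0894).
#' @param tol Termination bracket width in waves (default 1e-3).
#' @param scan_step Coarse scan step in waves (default 0.5).
#' @param a_max Scan bound in waves (default 50).
#' @return A one-row tibble: `direction`, `critical_value`,
#'   `residual_at_cv`, `unbounded`, `threshold`.
#' @export
find_critical_value <- function(residual_fn, direction = 1,
                                threshold = 0.0894, tol = 1e-3,
                                scan_step = 0.5, a_max = 50) {
  stopifnot(threshold > 0, tol > 0, scan_step > 0, a_max > 0,
            direction %in% c(-1, 1))
  res_at <- function(a) as.numeric(residual_fn(a))
  lo <- 0           # last passing amplitude (magnitude)
  r_lo <- res_at(0)
  hi <- NA
  a <- scan_step
  while (a <= a_max + 1e-12) {
    r <- res_at(direction * a)
    if (r > threshold) { hi <- a; break }
    lo <- a; r_lo <- r
    a <- a + scan_step
  }
  if (is.na(hi)) {
    return(tibble::tibble(direction = direction,
                          critical_value = direction * lo,
                          residual_at_cv = r_lo, unbounded = TRUE,
                          threshold = threshold))
  }
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    r <- res_at(direction * mid)
    if (r > threshold) hi <- mid else { lo <- mid; r_lo <- r }
  }
  tibble::tibble(direction = direction, critical_value = direction * lo,
                 residual_at_cv = r_lo, unbounded = FALSE,
                 threshold = threshold)
}

#' Dynamic range of a reconstructor for one mode and direction
#'
#' Rendering wrapper around [find_critical_value()].
#'
#' @inheritParams residual_for_amplitude
#' @inheritParams find_critical_value
#' @return The [find_critical_value()] tibble plus `mode`.
#' @export
dynamic_range <- function(reconstructor, j, direction = 1, geometry,
                          threshold = 0.0894, tol = 1e-3, scan_step = 0.5,
                          a_max = 50, ...) {
  out <- find_critical_value(
    function(a) residual_for_amplitude(reconstructor, j, a, geometry, ...),
    direction = direction, threshold = threshold, tol = tol,
    scan_step = scan_step, a_max = a_max)
  dplyr::bind_cols(tibble::tibble(mode = j), out)
}

#' Relative dynamic-range improvement
#'
#' `(cv_candidate - cv_reference) / cv_reference`; e.g. 1.86 renders as a
#' "186%" improvement over the reference reconstructor.
#'
#' @param cv_candidate,cv_reference Critical values in waves (reference
#'   nonzero).
#' @return Dimensionless improvement.
#' @export
dr_improvement <- function(cv_candidate, cv_reference) {
  if (any(cv_reference == 0)) stop("reference critical value is zero", call. = FALSE)
  (cv_candidate - cv_reference) / cv_reference
}

#' Sweep modes and reconstructors
#'
#' Runs the critical-value search for every (reconstructor, mode,
#' direction) combination and attaches each candidate's improvement over
#' the first reconstructor in the list (the baseline, conventionally the
#' modal method). Improvements compare critical-value magnitudes per
#' direction.
#'
#' @param reconstructors Named list of reconstructor functions; the first is
#'   the baseline.
#' @param modes OSA modes to sweep (default `3:9`, the low-order set that
#'   dominates ocular aberration power).
#' @param geometry A [shwfs_geometry()].
#' @inheritParams dynamic_range
#' @return A `dr_sweep` tibble: `reconstructor`, `mode`, `direction`,
#'   `critical_value`, `residual_at_cv`, `unbounded`, `threshold`,
#'   `improvement`.
#' @export
sweep_modes <- function(reconstructors, modes = 3:9, geometry,
                        threshold = 0.0894, tol = 1e-3, scan_step = 0.5,
                        a_max = 50, ...) {
  stopifnot(length(reconstructors) >= 1)
  if (is.null(names(reconstructors))) {
    names(reconstructors) <- paste0("recon", seq_along(reconstructors))
  }
  grid <- tidyr::expand_grid(reconstructor = names(reconstructors),
                             mode = modes, direction = c(1, -1))
  rows <- purrr::pmap(grid, function(reconstructor, mode, direction) {
    out <- dynamic_range(reconstructors[[reconstructor]], mode, direction,
                         geometry, threshold, tol, scan_step, a_max, ...)
    dplyr::bind_cols(tibble::tibble(reconstructor = reconstructor), out)
  })
  out <- dplyr::bind_rows(rows)
  base <- names(reconstructors)[1]
  ref <- dplyr::select(dplyr::filter(out, .data$reconstructor == base),
                       "mode", "direction", ref_cv = "critical_value")
  out <- dplyr::left_join(out, ref, by = c("mode", "direction"))
  out$improvement <- ifelse(out$ref_cv == 0, NA_real_,
                            (abs(out$critical_value) - abs(out$ref_cv)) /
                              abs(out$ref_cv))
  out$ref_cv <- NULL
  class(out) <- c("dr_sweep", class(out))
  out
}

#' Reconstructor factories for the protocol
#'
#' `reconstructor_modal()` wraps the classical pipeline (precomputing the
#' modal matrix); `reconstructor_cnn()` wraps a trained network, including
#' the downsampling/normalization step it was trained with;
#' `reconstructor_oracle()` returns the generating label carried by the
#' rendered Hartmannogram (perfect reconstruction; for protocol tests).
#'
#' @param geometry A [shwfs_geometry()] (modal).
#' @param ... Passed to [reconstruct_modal()].
#' @return A function `hartmannogram -> 44 coefficients`.
#' @export
reconstructor_modal <- function(geometry, ...) {
  mmat <- build_modal_matrix(geometry)
  function(h) reconstruct_modal(h, mmat, ...)
}

#' @rdname reconstructor_modal
#' @param fit A `cnn_fit`.
#' @param input_side Network input side used at training time.
#' @export
reconstructor_cnn <- function(fit, input_side = 64) {
  function(h) {
    img <- downsample_hartmannogram(h, input_side)
    as.numeric(predict_cnn(fit, img))
  }
}

#' @rdname reconstructor_modal
#' @export
reconstructor_oracle <- function() {
  function(h) h$coeffs
}
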