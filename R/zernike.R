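# Zernike polynomial machinery on the unit disk: OSA/ANSI single indexing,
# Noll normalization (disk average of Z_j^2 is 1 for j >= 1), evaluation,
# analytic Cartesian gradients, wavefront synthesis and RMS bookkeeping.
#
# Modes are represented internally as exact bivariate monomial expansions
# Z_j(x, y) = sum_t c_t x^{p_t} y^{q_t}, which makes evaluation and
# differentiation trivially exact everywhere on the disk (including rho = 0,
# where polar-form gradients are indeterminate).

#' Convert an OSA/ANSI single index to radial order and azimuthal frequency
#'
#' Under OSA/ANSI ordering `j = (n(n+2) + m)/2`, with modes sorted by radial
#' order `n` and, within an order, by ascending signed azimuthal frequency
#' `m`. Negative `m` denotes the sine harmonic, positive `m` the cosine
#' harmonic. Modes `j = 1..44` cover radial orders 1 through 8.
#'
#' @param j Integer vector of OSA indices (`>= 0`).
#' @return A tibble with columns `j`, `n`, `m`.
#' @examples
#' osa_to_nm(4)   # defocus: n = 2, m = 0
#' osa_to_nm(0:5)
#' @export
osa_to_nm <- function(j) {
  if (any(!is.finite(j)) || any(j < 0) || any(j != round(j))) {
    stop("OSA index `j` must be a non-negative integer", call. = FALSE)
  }
  j <- as.integer(round(j))
  n <- as.integer(ceiling((-3 + sqrt(9 + 8 * j)) / 2))
  m <- as.integer(2L * j - n * (n + 2L))
  tibble::tibble(j = j, n = n, m = m)
}

#' Convert radial order and azimuthal frequency to the OSA/ANSI single index
#'
#' @param n Radial order (integer `>= 0`).
#' @param m Signed azimuthal frequency; `|m| <= n` and `n - |m|` even.
#' @return Integer vector of OSA indices.
#' @examples
#' nm_to_osa(2, 0)  # 4
#' @export
nm_to_osa <- function(n, m) {
  if (any(n < 0) || any(n != round(n)) || any(abs(m) > n) ||
      any((n - abs(m)) %% 2 != 0)) {
    stop("invalid (n, m): need n >= 0, |m| <= n, n - |m| even", call. = FALSE)
  }
  as.integer((n * (n + 2) + m) / 2)
}

# Radial polynomial coefficients of R_n^{|m|}: named numeric vector mapping
# rho powers (n - 2s) to coefficients.
zernike_radial_coefs <- function(n, m_abs) {
  s <- 0:((n - m_abs) / 2)
  coef <- (-1)^s * factorial(n - s) /
    (factorial(s) * factorial((n + m_abs) / 2 - s) * factorial((n - m_abs) / 2 - s))
  stats::setNames(coef, n - 2 * s)
}

# Noll normalization constant so that the disk average of Z_j^2 equals 1.
zernike_norm <- function(n, m) {
  sqrt(2 * (n + 1) / (1 + as.numeric(m == 0)))
}

# Monomial expansion of one mode: data.frame(px, py, coef) with
# Z_j = sum coef * x^px * y^py on the unit disk. Exact (rational up to the
# normalization radical). Memoized.
.zernike_cache <- new.env(parent = emptyenv())

zernike_xy_poly <- function(j) {
  key <- as.character(j)
  hit <- .zernike_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- osa_to_nm(j)
  n <- idx$n; m <- idx$m; ma <- abs(m)
  rad <- zernike_radial_coefs(n, ma)
  # rho^k * cos(ma t) = (x^2+y^2)^{(k-ma)/2} * Re[(x+iy)^ma]; sine -> Im.
  terms <- list()
  for (k in as.integer(names(rad))) {
    ck <- rad[[as.character(k)]]
    e <- (k - ma) / 2
    # binomial expansion of (x^2 + y^2)^e
    for (u in 0:e) {
      bin_e <- choose(e, u)        # x^{2(e-u)} y^{2u}
      for (t in 0:ma) {
        # (x + iy)^ma term: C(ma,t) x^{ma-t} (iy)^t
        if (m >= 0) { # cosine: even t
          if (t %% 2 != 0) next
          c_tr <- choose(ma, t) * (-1)^(t / 2)
        } else {      # sine: odd t
          if (t %% 2 != 1) next
          c_tr <- choose(ma, t) * (-1)^((t - 1) / 2)
        }
        terms[[length(terms) + 1L]] <- c(
          px = ma - t + 2 * (e - u), py = t + 2 * u, coef = ck * bin_e * c_tr)
      }
    }
  }
  df <- as.data.frame(do.call(rbind, terms))
  df <- stats::aggregate(coef ~ px + py, df, sum)
  df <- df[abs(df$coef) > 1e-12, , drop = FALSE]
  df$coef <- df$coef * zernike_norm(n, m)
  rownames(df) <- NULL
  .zernike_cache[[key]] <- df
  df
}

# Combine a coefficient vector into one monomial table for fast synthesis.
zernike_poly_combine <- function(a, modes = seq_along(a)) {
  keep <- which(a != 0)
  if (length(keep) == 0) return(data.frame(px = 0, py = 0, coef = 0))
  parts <- lapply(keep, function(i) {
    df <- zernike_xy_poly(modes[i])
    df$coef <- df$coef * a[i]
    df
  })
  df <- do.call(rbind, parts)
  df <- stats::aggregate(coef ~ px + py, df, sum)
  df[abs(df$coef) > 0, , drop = FALSE]
}

# Evaluate a monomial table on the separable grid (xv columns, yv rows) via
# accumulated outer products; returns length(yv) x length(xv) matrix.
poly_eval_grid <- function(df, xv, yv) {
  out <- matrix(0, length(yv), length(xv))
  for (q in unique(df$py)) {
    sub <- df[df$py == q, , drop = FALSE]
    wx <- numeric(length(xv))
    for (r in seq_len(nrow(sub))) wx <- wx + sub$coef[r] * xv^sub$px[r]
    out <- out + outer(yv^q, wx)
  }
  out
}

poly_eval_points <- function(df, x, y) {
  out <- numeric(length(x))
  for (r in seq_len(nrow(df))) out <- out + df$coef[r] * x^df$px[r] * y^df$py[r]
  out
}

poly_deriv <- function(df, var = c("x", "y")) {
  var <- match.arg(var)
  if (var == "x") {
    df <- df[df$px > 0, , drop = FALSE]
    if (nrow(df) == 0) return(data.frame(px = 0, py = 0, coef = 0))
    data.frame(px = df$px - 1, py = df$py, coef = df$coef * df$px)
  } else {
    df <- df[df$py > 0, , drop = FALSE]
    if (nrow(df) == 0) return(data.frame(px = 0, py = 0, coef = 0))
    data.frame(px = df$px, py = df$py - 1, coef = df$coef * df$py)
  }
}

#' Evaluate a Zernike mode at polar coordinates
#'
#' Noll-normalized OSA/ANSI mode `Z_j(rho, theta)`; the disk average of
#' `Z_j^2` is 1 for every `j >= 1`. Scalar/vector calls reject points
#' outside the unit disk; use [wavefront_from_coeffs()] for masked grid
#' evaluation.
#'
#' @param j OSA index (scalar).
#' @param rho Normalized radius in `[0, 1]`.
#' @param theta Azimuth in radians.
#' @return Numeric vector of mode values (dimensionless).
#' @examples
#' zernike_eval(4, 1 / sqrt(2), 0)  # root of the defocus parabola
#' @export
zernike_eval <- function(j, rho, theta) {
  if (any(rho < 0) || any(rho > 1 + 1e-12)) {
    stop("rho must lie in [0, 1] for point evaluation", call. = FALSE)
  }
  df <- zernike_xy_poly(j)
  poly_eval_points(df, rho * cos(theta), rho * sin(theta))
}

#' Analytic Cartesian gradient of a Zernike mode
#'
#' Exact partial derivatives with respect to the normalized pupil coordinates
#' `(x, y) = (rho cos theta, rho sin theta)`, in waves per unit pupil radius
#' when the mode carries a coefficient of 1 wave.
#'
#' @inheritParams zernike_eval
#' @return A tibble with columns `dx`, `dy`.
#' @export
zernike_gradient <- function(j, rho, theta) {
  if (any(rho < 0) || any(rho > 1 + 1e-12)) {
    stop("rho must lie in [0, 1] for point evaluation", call. = FALSE)
  }
  df <- zernike_xy_poly(j)
  x <- rho * cos(theta); y <- rho * sin(theta)
  tibble::tibble(
    dx = poly_eval_points(poly_deriv(df, "x"), x, y),
    dy = poly_eval_points(poly_deriv(df, "y"), x, y))
}

#' Square sampling grid over the unit disk
#'
#' @param samples_per_side Number of samples per side.
#' @return A `pupil_grid` object: normalized coordinate vectors `x`, `y`
#'   (symmetric about the pupil center) and the inside-disk logical `mask`
#'   (`rho <= 1`).
#' @export
pupil_grid <- function(samples_per_side) {
  stopifnot(samples_per_side >= 2)
  n <- as.integer(samples_per_side)
  # pixel-center convention, symmetric about 0; full width 2 (radius 1)
  v <- (seq_len(n) - (n + 1) / 2) * (2 / n)
  rho2 <- outer(v^2, v^2, "+")
  structure(list(x = v, y = v, mask = rho2 <= 1, n = n), class = "pupil_grid")
}

#' Synthesize a wavefront map from Zernike coefficients
#'
#' `W(x, y) = sum_j a_j Z_j(x, y)` in waves on the in-mask samples of the
#' grid; samples outside the unit disk are `NA`.
#'
#' @param coeffs Numeric vector of coefficients in waves, element `i` being
#'   OSA mode `j = i` (piston excluded; default length 44).
#' @param grid A [pupil_grid()].
#' @return A `wavefront_map`: list with matrix `values` (rows index `y`) and
#'   the grid.
#' @export
wavefront_from_coeffs <- function(coeffs, grid) {
  stopifnot(inherits(grid, "pupil_grid"))
  check_coeffs(coeffs)
  df <- zernike_poly_combine(coeffs, modes = seq_along(coeffs))
  w <- poly_eval_grid(df, grid$x, grid$y)
  w[!grid$mask] <- NA_real_
  structure(list(values = w, grid = grid), class = "wavefront_map")
}

check_coeffs <- function(coeffs, k = NULL) {
  if (!is.numeric(coeffs) || any(!is.finite(coeffs))) {
    stop("Zernike coefficients must be finite numerics", call. = FALSE)
  }
  if (!is.null(k) && length(coeffs) != k) {
    stop(sprintf("expected %d coefficients, got %d", k, length(coeffs)),
         call. = FALSE)
  }
  invisible(coeffs)
}

#' Wavefront RMS from Zernike coefficients
#'
#' By orthonormality of the basis, the over-the-pupil RMS of the zero-mean
#' wavefront equals `sqrt(sum of squared coefficients)`. Tilt/tip are usually
#' excluded when quoting ocular aberration magnitudes.
#'
#' @param coeffs Coefficient vector (waves), element `i` = OSA mode `i`.
#' @param exclude Integer set of OSA modes to drop (e.g. `c(1, 2)` for
#'   tilt/tip); default none.
#' @return RMS in waves.
#' @export
wavefront_rms <- function(coeffs, exclude = integer()) {
  check_coeffs(coeffs)
  if (length(exclude) && (any(exclude < 1) || any(exclude > length(coeffs)))) {
    stop("`exclude` must be a subset of 1..length(coeffs)", call. = FALSE)
  }
  keep <- setdiff(seq_along(coeffs), exclude)
  sqrt(sum(coeffs[keep]^2))
}

#' Project a wavefront map onto the Zernike basis
#'
#' Mask-weighted inner products on the sampling grid; used mainly as an
#' independent route to recover coefficients in tests.
#'
#' @param wf A `wavefront_map`.
#' @param modes OSA indices to project onto.
#' @return Named numeric vector of coefficients in waves.
#' @export
project_wavefront <- function(wf, modes = 1:44) {
  stopifnot(inherits(wf, "wavefront_map"))
  g <- wf$grid
  m <- g$mask
  w <- wf$values[m]
  vapply(modes, function(j) {
    z <- poly_eval_grid(zernike_xy_poly(j), g$x, g$y)[m]
    sum(w * z) / sum(z * z)
  }, numeric(1)) |> stats::setNames(paste0("Z", modes))
}

#' Tabulate the Zernike modes in use
#'
#' @param modes OSA indices (default the standard 44-mode ophthalmic set).
#' @return Tibble with `j`, `n`, `m` and the conventional aberration name of
#'   the low-order modes.
#' @export
zernike_table <- function(modes = 1:44) {
  tab <- osa_to_nm(modes)
  nm <- rep(NA_character_, nrow(tab))
  nm[tab$j %in% 1:2] <- "tilt"
  nm[tab$j %in% c(3, 5)] <- "astigmatism"
  nm[tab$j == 4] <- "defocus"
  nm[tab$j %in% c(6, 9)] <- "trefoil"
  nm[tab$j %in% c(7, 8)] <- "coma"
  nm[tab$j == 12] <- "spherical"
  tab$name <- nm
  tab
}
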