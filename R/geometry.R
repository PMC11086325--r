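# Sensor geometry: lenslet-array and detector bookkeeping. All lengths are
# stored in meters; constructors accept the conventional mixed units used on
# instrument datasheets (mm / nm / um) via `shwfs_geometry()` arguments.

#' Shack-Hartmann sensor geometry
#'
#' Validates and derives the raster bookkeeping of a square-lenslet
#' Shack-Hartmann sensor: the detector cell assigned to each lenslet must
#' contain a near-integer number of pixels (`lenslet_pitch / pixel_pitch`
#' within 0.01 px of an integer) and the detector side is
#' `lenslet_count * pixels_per_subaperture`.
#'
#' The default arguments describe the simulated ophthalmic sensor profile
#' used throughout: 6 mm pupil, 840 nm source, 20x20 lenslets of 300 um at
#' f = 15 mm, 6.5217 um pixels, giving 46 px sub-apertures on a 920 px
#' detector.
#'
#' @param pupil_diameter_mm Eye pupil diameter imaged onto the lenslet array.
#' @param wavelength_nm Source wavelength.
#' @param lenslet_count Lenslets per side.
#' @param lenslet_pitch_um Lenslet pitch (square lenslets, fill factor 1).
#' @param focal_length_mm Lenslet focal length.
#' @param pixel_pitch_um Detector pixel pitch.
#' @param aperture_to_mla_mm Free-space propagation distance between the
#'   pupil/aperture plane and the lenslet array. The default 0 models the
#'   standard aberrometer layout in which relay optics conjugate the eye
#'   pupil onto the lenslet array; a nonzero distance (e.g. the focal
#'   length, for the front-focal-plane layout) inserts a Fresnel
#'   propagation step, whose beam magnification under defocus then becomes
#'   part of the measured response.
#' @param pupil_shape `"disk"` (default; circular pupil of
#'   `pupil_diameter`, the ophthalmic case) or `"square"` (the whole
#'   lenslet-array aperture is illuminated; the idealized configuration in
#'   which all sub-apertures are symmetric).
#' @return A `shwfs_geometry` object (all fields in meters plus derived
#'   integer raster sizes).
#' @examples
#' g <- shwfs_geometry()
#' g$detector_side_px          # 920
#' g$pixels_per_subaperture    # 46
#' @export
shwfs_geometry <- function(pupil_diameter_mm = 6,
                           wavelength_nm = 840,
                           lenslet_count = 20,
                           lenslet_pitch_um = 300,
                           focal_length_mm = 15,
                           pixel_pitch_um = 6.5217,
                           aperture_to_mla_mm = 0,
                           pupil_shape = c("disk", "square")) {
  pupil_shape <- match.arg(pupil_shape)
  stopifnot(is.finite(aperture_to_mla_mm), aperture_to_mla_mm >= 0)
  num <- c(pupil_diameter_mm, wavelength_nm, lenslet_count,
           lenslet_pitch_um, focal_length_mm, pixel_pitch_um)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all geometry parameters must be positive and finite", call. = FALSE)
  }
  lenslet_count <- as.integer(lenslet_count)
  g <- list(
    pupil_diameter = pupil_diameter_mm * 1e-3,
    wavelength     = wavelength_nm * 1e-9,
    lenslet_count  = lenslet_count,
    lenslet_pitch  = lenslet_pitch_um * 1e-6,
    focal_length   = focal_length_mm * 1e-3,
    pixel_pitch    = pixel_pitch_um * 1e-6,
    aperture_to_mla = aperture_to_mla_mm * 1e-3,
    pupil_shape    = pupil_shape)
  ratio <- g$lenslet_pitch / g$pixel_pitch
  ppsa <- round(ratio)
  if (abs(ratio - ppsa) >= 0.01) {
    stop(sprintf(paste0(
      "lenslet_pitch / pixel_pitch = %.4f px is not within 0.01 px of an ",
      "integer; choose a pixel pitch that tiles the sub-aperture"), ratio),
      call. = FALSE)
  }
  g$pixels_per_subaperture <- as.integer(ppsa)
  g$detector_side_px <- g$lenslet_count * g$pixels_per_subaperture
  g$aperture_side <- g$lenslet_count * g$lenslet_pitch
  if (g$pupil_diameter > g$aperture_side + 1e-12) {
    stop("pupil_diameter exceeds the lenslet-array aperture", call. = FALSE)
  }
  structure(g, class = "shwfs_geometry")
}

#' Named geometry profiles
#'
#' `"table1"` is the full-scale simulated instrument (20x20 lenslets, 920 px
#' detector). `"mini"` keeps the 46 px sub-aperture sampling but uses an
#' 8x8 lenslet array over a 2.4 mm pupil (368 px detector) so that the
#' classical-path and dynamic-range protocols run quickly. `"micro"` uses
#' 8x8 lenslets with 16 px sub-apertures (128 px detector), sized for CNN
#' training experiments on a single CPU.
#'
#' @param name One of `"table1"`, `"mini"`, `"micro"`.
#' @return A `shwfs_geometry`.
#' @export
shwfs_geometry_profile <- function(name = c("table1", "mini", "micro")) {
  switch(match.arg(name),
    table1 = shwfs_geometry(),
    mini   = shwfs_geometry(pupil_diameter_mm = 2.4, lenslet_count = 8),
    micro  = shwfs_geometry(pupil_diameter_mm = 2.4, lenslet_count = 8,
                            pixel_pitch_um = 300 / 16))
}

#' @export
print.shwfs_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<shwfs_geometry> %dx%d lenslets (%.0f um pitch), f = %.1f mm\n",
    "  pupil %.2f mm, lambda %.0f nm, pixel %.4f um\n",
    "  detector %d px, %d px per sub-aperture\n"),
    x$lenslet_count, x$lenslet_count, x$lenslet_pitch * 1e6,
    x$focal_length * 1e3, x$pupil_diameter * 1e3, x$wavelength * 1e9,
    x$pixel_pitch * 1e6, x$detector_side_px, x$pixels_per_subaperture))
  invisible(x)
}

#' Sub-aperture layout table
#'
#' One row per lenslet cell: 0-based `(row, col)` indices (row-major from the
#' top-left of the detector), detector-pixel cell centers (0-based pixel
#' centers), normalized pupil coordinates of the cell center, and whether the
#' cell lies in the pupil (at least half its area inside the unit disk,
#' judged on a fine sub-grid).
#'
#' @param geometry A [shwfs_geometry()].
#' @param subgrid Per-cell sampling used for the area fraction (default 11).
#' @return Tibble with columns `row`, `col`, `cx_px`, `cy_px`, `ux`, `uy`,
#'   `in_pupil`, `inside_frac`.
#' @export
subaperture_table <- function(geometry, subgrid = 11) {
  nl <- geometry$lenslet_count
  ppsa <- geometry$pixels_per_subaperture
  rr <- rep(0:(nl - 1), each = nl)
  cc <- rep(0:(nl - 1), times = nl)
  # cell center in detector px, 0-based pixel-center convention
  cx <- (cc + 0.5) * ppsa - 0.5
  cy <- (rr + 0.5) * ppsa - 0.5
  # normalized pupil coordinates of the cell center; detector pixel k has
  # physical center ((k + 0.5) * pitch_eff - side/2)
  pitch_eff <- geometry$lenslet_pitch / ppsa
  half <- geometry$aperture_side / 2
  r_pupil <- geometry$pupil_diameter / 2
  ux <- ((cx + 0.5) * pitch_eff - half) / r_pupil
  uy <- ((cy + 0.5) * pitch_eff - half) / r_pupil
  # fraction of cell area inside the pupil
  if (identical(geometry$pupil_shape, "square")) {
    frac <- rep(1, length(ux))
  } else {
    off <- (seq_len(subgrid) - (subgrid + 1) / 2) / subgrid *
      (geometry$lenslet_pitch / r_pupil)
    frac <- vapply(seq_along(ux), function(i) {
      mean(outer(uy[i] + off, ux[i] + off, function(a, b) a^2 + b^2) <= 1)
    }, numeric(1))
  }
  tibble::tibble(row = rr, col = cc, cx_px = cx, cy_px = cy,
                 ux = ux, uy = uy, inside_frac = frac,
                 in_pupil = frac >= 0.5)
}
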