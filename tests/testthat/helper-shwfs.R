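# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

geom_micro <- function() cached("micro", shwfs_geometry_profile("micro"))
geom_mini <- function() cached("mini", shwfs_geometry_profile("mini"))
geom_micro_sq <- function() cached("micro_sq",
  shwfs_geometry(pupil_diameter_mm = 2.4, lenslet_count = 8,
                 pixel_pitch_um = 300 / 16, pupil_shape = "square"))

mm_micro <- function() cached("mm_micro", build_modal_matrix(geom_micro()))
mm_mini <- function() cached("mm_mini", build_modal_matrix(geom_mini()))

render_cached <- function(key, coeffs, geometry, ...) {
  cached(key, render_hartmannogram(coeffs, geometry, ...))
}

# coefficients scaled so the largest predicted in-pupil spot displacement is
# `fraction` of the half-pitch (the in-range regime)
scale_in_range <- function(coeffs, geometry, fraction = 0.6) {
  o <- spot_displacement_oracle(coeffs, geometry)
  dmax <- max(sqrt(o$dx_px^2 + o$dy_px^2)[o$in_pupil])
  target <- fraction * geometry$pixels_per_subaperture / 2
  if (dmax > target) coeffs * target / dmax else coeffs
}

# distance (in lenslet rings) of each sub-aperture from the array border
cell_ring <- function(cells, geometry) {
  n <- geometry$lenslet_count - 1
  pmin(pmin(cells$row, n - cells$row), pmin(cells$col, n - cells$col))
}

unit_coeffs <- function(j, a = 1, k = 44) {
  co <- rep(0, k)
  co[j] <- a
  co
}
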