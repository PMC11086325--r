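# File interfaces: coefficient CSV/JSON, run configuration (YAML
# key-value), 16-bit TIFF raster export with JSON sidecar metadata,
# directory-based dataset serialization, and the deterministic fixture
# bundle used by the test suite.

#' Read / write Zernike coefficient files
#'
#' CSV with header `j,value_waves` (one row per OSA mode) or the JSON
#' equivalent (object with `j` and `value_waves` arrays); both round-trip at
#' full double precision.
#'
#' @param path File path (`.csv` or `.json` decides the format).
#' @return Numeric coefficient vector indexed by OSA mode `1..max(j)`.
#' @export
read_zernike_coeffs <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    d <- utils::read.csv(path)
  }
  stopifnot(all(c("j", "value_waves") %in% names(d)))
  out <- rep(0, max(d$j))
  out[d$j] <- d$value_waves
  out
}

#' @rdname read_zernike_coeffs
#' @param coeffs Coefficient vector (element `i` = OSA mode `i`).
#' @export
write_zernike_coeffs <- function(coeffs, path) {
  d <- data.frame(j = seq_along(coeffs), value_waves = as.numeric(coeffs))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(d), path, digits = I(17), auto_unbox = FALSE)
  } else {
    writeLines(c("j,value_waves",
                 sprintf("%d,%.17g", d$j, d$value_waves)), path)
  }
  invisible(path)
}

config_keys <- list(
  geometry = c("pupil_diameter_mm", "wavelength_nm", "lenslet_count",
               "lenslet_pitch_um", "focal_length_mm", "pixel_pitch_um",
               "aperture_to_mla_mm", "pupil_shape"),
  eye_model = c("mu", "sigma_diag", "sigma"),
  dataset = c("n_train", "n_val", "n_test", "input_side", "oversample", "seed"),
  train = c("profile", "epochs", "batch_size", "lr0", "weight_decay",
            "lr_end_factor", "seed"),
  protocol = c("threshold", "tol", "scan_step", "a_max", "modes"))

#' Load a run configuration
#'
#' YAML file with optional sections `geometry`, `eye_model`, `dataset`,
#' `train`, `protocol`. Unknown sections or keys are rejected by name;
#' geometry lengths carry their units in the key names (`*_mm`, `*_nm`,
#' `*_um`) and must be positive. Missing values fall back to package
#' defaults (an empty file yields the full-scale default geometry).
#'
#' @param path YAML file path.
#' @return A `run_config` list with `geometry` (a [shwfs_geometry()]),
#'   `eye_model` (an [eye_model()]), and the remaining sections as lists of
#'   resolved values.
#' @export
load_config <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path, call. = FALSE)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(config_keys))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), config_keys[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in section `%s`: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  gsec <- cfg$geometry %||% list()
  geometry <- do.call(shwfs_geometry, gsec)
  eye <- if (is.null(cfg$eye_model)) default_eye_model() else {
    mu <- as.numeric(cfg$eye_model$mu %||% rep(0, 44))
    if (!is.null(cfg$eye_model$sigma)) {
      eye_model(mu, sigma = do.call(rbind, lapply(cfg$eye_model$sigma, as.numeric)))
    } else if (!is.null(cfg$eye_model$sigma_diag)) {
      eye_model(mu, sigma_diag = as.numeric(cfg$eye_model$sigma_diag))
    } else default_eye_model()
  }
  dataset <- utils::modifyList(
    list(n_train = 24000, n_val = 8000, n_test = 8000, input_side = 200,
         oversample = 2, seed = 1), cfg$dataset %||% list())
  train <- utils::modifyList(
    list(profile = "paper", epochs = 500, batch_size = 8, lr0 = 3e-4,
         weight_decay = 0.05, lr_end_factor = 1e-6, seed = 1),
    cfg$train %||% list())
  protocol <- utils::modifyList(
    list(threshold = 0.0894, tol = 1e-3, scan_step = 0.5, a_max = 50,
         modes = 3:9), cfg$protocol %||% list())
  structure(list(geometry = geometry, eye_model = eye, dataset = dataset,
                 train = train, protocol = protocol, path = path),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a Hartmannogram as 16-bit TIFF with JSON sidecar
#'
#' Intensities are max-normalized and quantized to 16 bits (worst-case
#' quantization error 1/65535 of full scale); the sidecar records the
#' normalization constant, geometry, and the label coefficients, so
#' `read_hartmannogram_tiff()` restores intensities up to quantization.
#'
#' @param h A `hartmannogram`.
#' @param path TIFF path (sidecar written at `<path>.json`).
#' @export
write_hartmannogram_tiff <- function(h, path) {
  stopifnot(inherits(h, "hartmannogram"))
  mx <- max(h$intensity)
  img <- if (mx > 0) h$intensity / mx else h$intensity
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  g <- h$geometry
  jsonlite::write_json(list(
    max_intensity = mx, energy_kept = h$energy_kept,
    oversample = h$oversample, coeffs = as.numeric(h$coeffs),
    geometry = list(pupil_diameter_mm = g$pupil_diameter * 1e3,
                    wavelength_nm = g$wavelength * 1e9,
                    lenslet_count = g$lenslet_count,
                    lenslet_pitch_um = g$lenslet_pitch * 1e6,
                    focal_length_mm = g$focal_length * 1e3,
                    pixel_pitch_um = g$pixel_pitch * 1e6)),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hartmannogram_tiff
#' @export
read_hartmannogram_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geometry <- do.call(shwfs_geometry, as.list(meta$geometry))
  h <- new_hartmannogram(img * meta$max_intensity, geometry,
                         coeffs = as.numeric(meta$coeffs),
                         energy_kept = meta$energy_kept,
                         oversample = meta$oversample)
  h
}

#' Deterministic fixture bundle
#'
#' Eight coefficient vectors spanning the normal (every spot in its home
#' cell) and abnormal (spots crossing cells) regimes, their rendered
#' Hartmannograms at the requested geometry, and the ray-oracle centroid
#' predictions — a compact, reproducible bundle for tests that should not
#' re-run the physics repeatedly.
#'
#' @param seed Integer seed.
#' @param geometry A [shwfs_geometry()] (default the fast `"micro"`
#'   profile).
#' @return List with `coeffs` (8 x 44), `regime`, `hartmannograms`,
#'   `oracle` (list of [spot_displacement_oracle()] tables), `geometry`,
#'   `seed`.
#' @export
make_fixtures <- function(seed = 1, geometry = shwfs_geometry_profile("micro")) {
  model <- default_eye_model()
  raw <- sample_eye_coeffs(model, 8, seed = seed)
  # scale the first six into the in-range regime, leave two abnormal
  half_pitch_px <- geometry$pixels_per_subaperture / 2
  coeffs <- raw
  regime <- character(8)
  for (i in 1:8) {
    o <- spot_displacement_oracle(raw[i, ], geometry)
    dmax <- max(sqrt(o$dx_px^2 + o$dy_px^2)[o$in_pupil])
    if (i <= 6) {
      target <- 0.6 * half_pitch_px
      if (dmax > target) coeffs[i, ] <- raw[i, ] * target / dmax
      regime[i] <- "normal"
    } else {
      target <- 2.5 * half_pitch_px
      if (dmax < target) coeffs[i, ] <- raw[i, ] * target / dmax
      regime[i] <- "abnormal"
    }
  }
  hs <- lapply(1:8, function(i) render_hartmannogram(coeffs[i, ], geometry))
  oracle <- lapply(1:8, function(i) spot_displacement_oracle(coeffs[i, ], geometry))
  list(coeffs = coeffs, regime = regime, hartmannograms = hs,
       oracle = oracle, geometry = geometry, seed = seed)
}

#' Write / read a dataset as a directory of TIFF rasters and CSV labels
#'
#' Each split becomes `<split>_NNNN.tif` rasters (16-bit, already
#' normalized to `[0, 1]`) plus `labels_<split>.csv`; `meta.json` records
#' the geometry, input side and seed. Quantization bounds the raster
#' round-trip error by 1/65535 of full scale; labels round-trip exactly.
#'
#' @param dataset A `shwfs_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_shwfs_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  splits <- intersect(names(dataset), c("train", "val", "test"))
  g <- dataset$geometry
  for (nm in splits) {
    sp <- dataset[[nm]]
    n <- dim(sp$images)[3]
    for (i in seq_len(n)) {
      tiff::writeTIFF(sp$images[, , i],
                      file.path(dir, sprintf("%s_%04d.tif", nm, i)),
                      bits.per.sample = 16)
    }
    lab_lines <- apply(sp$labels, 1, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(c(paste(paste0("Z", seq_len(ncol(sp$labels))), collapse = ","),
                 lab_lines), file.path(dir, sprintf("labels_%s.csv", nm)))
  }
  jsonlite::write_json(list(
    input_side = dataset$input_side, seed = dataset$seed,
    splits = splits,
    geometry = list(pupil_diameter_mm = g$pupil_diameter * 1e3,
                    wavelength_nm = g$wavelength * 1e9,
                    lenslet_count = g$lenslet_count,
                    lenslet_pitch_um = g$lenslet_pitch * 1e6,
                    focal_length_mm = g$focal_length * 1e3,
                    pixel_pitch_um = g$pixel_pitch * 1e6)),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_shwfs_dataset
#' @export
read_shwfs_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  geometry <- do.call(shwfs_geometry, as.list(meta$geometry))
  out <- list()
  for (nm in meta$splits) {
    lab <- as.matrix(utils::read.csv(file.path(dir, sprintf("labels_%s.csv", nm))))
    dimnames(lab) <- NULL
    n <- nrow(lab)
    side <- meta$input_side
    imgs <- array(0, c(side, side, n))
    for (i in seq_len(n)) {
      imgs[, , i] <- tiff::readTIFF(file.path(dir, sprintf("%s_%04d.tif", nm, i)))
    }
    out[[nm]] <- list(images = imgs, labels = lab)
  }
  structure(c(out, list(geometry = geometry, input_side = meta$input_side,
                        seed = meta$seed)),
            class = "shwfs_dataset")
}
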