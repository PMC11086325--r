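# Dataset generation and evaluation statistics for the learned
# reconstructor, plus the limited-data and turbulence-generalization
# harnesses.

#' Generate a labeled Hartmannogram dataset
#'
#' Coefficients are drawn from the population model, each is rendered
#' through the physical-optics chain, downsampled by bicubic interpolation
#' to the network input size and max-normalized to `[0, 1]`; the label is
#' the generating coefficient vector. Splits are disjoint by construction
#' and the whole dataset is reproducible from `seed`.
#'
#' @param counts Named vector `c(train = , val = , test = )` (any subset).
#' @param model An [eye_model()] (or any object accepted by `sampler`).
#' @param geometry A [shwfs_geometry()].
#' @param input_side Downsampled raster side fed to the network.
#' @param oversample Pupil oversampling for rendering.
#' @param seed Integer seed.
#' @param sampler Function `(model, n, seed) -> n x 44 matrix`; defaults to
#'   [sample_eye_coeffs()].
#' @param keep_raw Keep the full-resolution rasters too (memory permitting).
#' @return A `shwfs_dataset`: per split a list with `images`
#'   (`input_side x input_side x n`), `labels` (`n x 44`), optionally `raw`;
#'   plus `geometry`, `input_side`, `seed`.
#' @export
generate_shwfs_dataset <- function(counts, model = default_eye_model(),
                                   geometry = shwfs_geometry_profile("micro"),
                                   input_side = 64, oversample = 2, seed = 1,
                                   sampler = sample_eye_coeffs,
                                   keep_raw = FALSE) {
  stopifnot(all(counts >= 0))
  if (is.null(names(counts))) names(counts) <- c("train", "val", "test")[seq_along(counts)]
  total <- sum(counts)
  coeffs <- sampler(model, total, seed)
  splits <- list()
  offset <- 0
  for (nm in names(counts)) {
    n <- counts[[nm]]
    imgs <- array(0, c(input_side, input_side, max(n, 0)))
    raw <- if (keep_raw) array(0, c(geometry$detector_side_px,
                                    geometry$detector_side_px, max(n, 0)))
    for (i in seq_len(n)) {
      h <- render_hartmannogram(coeffs[offset + i, ], geometry, oversample)
      imgs[, , i] <- downsample_hartmannogram(h, input_side)
      if (keep_raw) raw[, , i] <- h$intensity
    }
    splits[[nm]] <- list(images = imgs,
                         labels = coeffs[offset + seq_len(n), , drop = FALSE],
                         raw = raw)
    offset <- offset + n
  }
  structure(c(splits, list(geometry = geometry, input_side = input_side,
                           seed = seed)),
            class = "shwfs_dataset")
}

#' Reconstruction statistics for a set of predictions
#'
#' Per-sample residual wavefront RMS (tilt/tip excluded), the summary the
#' benchmarking protocol reports: mean and population SD of the residual
#' RMS, mean/SD of the true and estimated wavefront RMS, and the fraction
#' of samples whose residual is below the Marechal criterion (1/14 wave:
#' diffraction-limited recovery).
#'
#' @param pred,labels `n x 44` coefficient matrices (waves).
#' @param marechal Pass threshold in waves (default `1/14`).
#' @return A `shwfs_eval`: list with per-sample tibble `samples` and
#'   one-row tibble `summary`.
#' @export
evaluate_predictions <- function(pred, labels, marechal = 1 / 14) {
  if (is.vector(pred)) pred <- matrix(pred, 1)
  if (is.vector(labels)) labels <- matrix(labels, 1)
  stopifnot(nrow(pred) == nrow(labels), ncol(pred) == ncol(labels))
  res <- residual_rms(labels, pred, exclude_tilt = TRUE)
  true_rms <- apply(labels, 1, wavefront_rms, exclude = 1:2)
  est_rms <- apply(pred, 1, wavefront_rms, exclude = 1:2)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  samples <- tibble::tibble(sample = seq_along(res), true_rms = true_rms,
                            est_rms = est_rms, residual_rms = res,
                            pass = res < marechal)
  summary <- tibble::tibble(
    n = length(res),
    rmse_mean = mean(res), rmse_sd = pop_sd(res),
    true_rms_mean = mean(true_rms), true_rms_sd = pop_sd(true_rms),
    est_rms_mean = mean(est_rms), est_rms_sd = pop_sd(est_rms),
    pass_rate = mean(samples$pass), marechal = marechal)
  structure(list(samples = samples, summary = summary), class = "shwfs_eval")
}

#' Evaluate a trained network on a labeled split
#'
#' @param fit A `cnn_fit` (or `cnn_model`).
#' @param testset List with `images` and `labels` (e.g. a dataset split).
#' @inheritParams evaluate_predictions
#' @return A `shwfs_eval`.
#' @export
evaluate_cnn <- function(fit, testset, marechal = 1 / 14) {
  pred <- predict_cnn(fit, testset$images)
  evaluate_predictions(pred, testset$labels, marechal)
}

#' @export
print.shwfs_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<shwfs_eval> n = %d\n  residual RMS %.4f +/- %.4f waves",
    " (pass rate %.2f%% at %.4f)\n  true RMS %.3f +/- %.3f,",
    " estimated RMS %.3f +/- %.3f\n"),
    s$n, s$rmse_mean, s$rmse_sd, 100 * s$pass_rate, s$marechal,
    s$true_rms_mean, s$true_rms_sd, s$est_rms_mean, s$est_rms_sd))
  invisible(x)
}

#' Training-set-size experiment
#'
#' Retrains the same architecture on nested random subsets of the training
#' pool and evaluates each on the shared test split, tracing how accuracy
#' and the Marechal pass rate scale with data volume.
#'
#' @param dataset A `shwfs_dataset` with `train` and `test` splits.
#' @param sizes Training-set sizes (each `<=` the pool size).
#' @param cfg A [cnn_config()].
#' @param epochs,batch_size,lr0,weight_decay,... Training recipe shared
#'   across sizes (see [train_cnn()]).
#' @param seed Seed controlling subset draws, init and shuffling.
#' @return Tibble with one row per size: `size`, `rmse_mean`, `rmse_sd`,
#'   `pass_rate`.
#' @export
limited_data_experiment <- function(dataset, sizes, cfg, epochs = 10,
                                    batch_size = 8, lr0 = 3e-4,
                                    weight_decay = 0.05, seed = 1, ...) {
  pool <- dim(dataset$train$images)[3]
  if (any(sizes > pool)) stop("requested size exceeds the training pool", call. = FALSE)
  rows <- lapply(seq_along(sizes), function(k) {
    sz <- sizes[k]
    idx <- withr::with_seed(seed + k, sample.int(pool, sz))
    sub <- list(images = dataset$train$images[, , idx, drop = FALSE],
                labels = dataset$train$labels[idx, , drop = FALSE])
    model <- init_cnn(cfg, seed = seed)
    fit <- train_cnn(model, sub, val = dataset$val, epochs = epochs,
                     batch_size = batch_size, lr0 = lr0,
                     weight_decay = weight_decay, seed = seed + k, ...)
    ev <- evaluate_cnn(fit, dataset$test)
    tibble::tibble(size = sz, rmse_mean = ev$summary$rmse_mean,
                   rmse_sd = ev$summary$rmse_sd,
                   pass_rate = ev$summary$pass_rate)
  })
  dplyr::bind_rows(rows)
}

#' Turbulence generalization test
#'
#' Renders aberrations drawn from Kolmogorov statistics — a distribution the
#' network never saw during training — and evaluates the trained weights on
#' them without any retraining.
#'
#' @param fit A trained `cnn_fit`.
#' @param turbulence A [turbulence_model()].
#' @param n Number of samples.
#' @param geometry,input_side,oversample Rendering setup (must match
#'   training).
#' @param seed Seed for the turbulence draw.
#' @return A `shwfs_eval` (empty tibbles when `n = 0`).
#' @export
generalization_test <- function(fit, turbulence, n, geometry,
                                input_side = 64, oversample = 2, seed = 1) {
  if (n == 0) {
    return(structure(list(samples = tibble::tibble(),
                          summary = tibble::tibble(n = 0L)),
                     class = "shwfs_eval"))
  }
  ds <- generate_shwfs_dataset(c(test = n), model = turbulence,
                               geometry = geometry, input_side = input_side,
                               oversample = oversample, seed = seed,
                               sampler = sample_kolmogorov_coeffs)
  evaluate_cnn(fit, ds$test)
}
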