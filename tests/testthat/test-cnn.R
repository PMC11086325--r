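# Convolutional regressor: contracts, gradients, schedule, training loop,
# and evaluation statistics.

tiny_cfg <- function() {
  cnn_config(input_side = 16, depths = c(1, 1, 1, 1), widths = c(4, 6, 8, 10),
             dw_kernel = 3, patch = 2, n_out = 5, layer_scale_init = 0.5)
}

test_that("forward pass honours the shape contract and is deterministic", {
  cfg <- cnn_profile("desk")
  expect_equal(cfg$depths, c(2, 2, 4, 2))
  expect_equal(cnn_profile("paper")$widths, c(96, 192, 384, 768))
  expect_equal(cfg$n_out, 44)
  m <- init_cnn(cfg, seed = 1)
  img <- matrix(runif(64 * 64), 64)
  out1 <- predict_cnn(m, img)
  expect_equal(dim(out1), c(1L, 44L))
  expect_true(all(is.finite(out1)))
  expect_identical(out1, predict_cnn(m, img))
  # batched predictions equal single-input calls
  imgs <- array(runif(64 * 64 * 3), c(64, 64, 3))
  batch <- predict_cnn(m, imgs)
  singles <- t(vapply(1:3, function(i) predict_cnn(m, imgs[, , i])[1, ],
                      numeric(44)))
  expect_equal(batch, singles, tolerance = 1e-10)
  expect_error(init_cnn(cnn_config(input_side = 63)), "input_side")
})

test_that("hand-written backprop matches finite differences", {
  set.seed(42)
  m <- init_cnn(tiny_cfg(), seed = 3)
  imgs <- array(runif(16 * 16 * 2), c(16, 16, 2))
  lab <- matrix(rnorm(10), 2)
  fw <- shwfsr:::cnn_forward(m, imgs, keep_cache = TRUE)
  gr <- shwfsr:::cnn_backward(m, fw$cache, 2 * (fw$out - lab) / length(lab))
  eps <- 1e-6
  for (nm in names(gr)) {
    i <- sample(length(gr[[nm]]), 1)
    m2 <- m
    m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    lp <- shwfsr:::mse_loss(shwfsr:::cnn_forward(m2, imgs)$out, lab)
    m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * eps
    lm <- shwfsr:::mse_loss(shwfsr:::cnn_forward(m2, imgs)$out, lab)
    fd <- (lp - lm) / (2 * eps)
    expect_equal(gr[[nm]][i], fd, tolerance = 1e-3,
                 label = paste("grad", nm))
  }
})

test_that("the cosine schedule decays monotonically to lr0 * 1e-6", {
  lrs <- vapply(1:30, shwfsr:::schedule_lr, numeric(1),
                total_epochs = 30, lr0 = 3e-4)
  expect_equal(lrs[1], 3e-4)
  expect_equal(lrs[30], 3e-10)
  expect_true(all(diff(lrs) < 0))
  # warmup rises linearly then decays
  lrw <- vapply(1:30, shwfsr:::schedule_lr, numeric(1),
                total_epochs = 30, lr0 = 3e-4, warmup_epochs = 5)
  expect_true(all(diff(lrw[1:5]) > 0))
  expect_equal(lrw[5], 3e-4)
  expect_equal(lrw[30], 3e-10)
})

test_that("zero-epoch training returns the initialized weights unchanged", {
  m <- init_cnn(tiny_cfg(), seed = 9)
  imgs <- array(runif(16 * 16 * 4), c(16, 16, 4))
  lab <- matrix(rnorm(20), 4)
  fit <- train_cnn(m, list(images = imgs, labels = lab), epochs = 0)
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history), 0)
})

test_that("a few optimizer steps reduce the loss on a small batch", {
  m <- init_cnn(tiny_cfg(), seed = 2)
  set.seed(14)
  imgs <- array(runif(16 * 16 * 8), c(16, 16, 8))
  lab <- matrix(rnorm(40), 8)
  fit <- train_cnn(m, list(images = imgs, labels = lab), epochs = 80,
                   batch_size = 8, lr0 = 2e-3, weight_decay = 0,
                   warmup_epochs = 10, standardize_labels = TRUE, seed = 4)
  h <- fit$history
  expect_lt(utils::tail(h$train_loss, 1), 0.5 * h$train_loss[1])
  # reruns with the same seed are identical
  fit2 <- train_cnn(init_cnn(tiny_cfg(), seed = 2),
                    list(images = imgs, labels = lab), epochs = 80,
                    batch_size = 8, lr0 = 2e-3, weight_decay = 0,
                    warmup_epochs = 10, standardize_labels = TRUE, seed = 4)
  expect_equal(fit$final_model$params, fit2$final_model$params,
               tolerance = 1e-12)
})

test_that("label standardization round-trips through prediction", {
  m <- init_cnn(tiny_cfg(), seed = 5)
  imgs <- array(runif(16 * 16 * 6), c(16, 16, 6))
  lab <- matrix(rnorm(30, sd = rep(c(5, 0.01, 1, 2, 0.5), each = 6)), 6)
  fit <- train_cnn(m, list(images = imgs, labels = lab), epochs = 2,
                   lr0 = 1e-4, seed = 1)
  pred <- predict_cnn(fit, imgs)
  expect_equal(dim(pred), dim(lab))
  # de-standardized predictions live on the label scale, not the unit scale
  expect_gt(stats::sd(pred[, 1]), stats::sd(pred[, 2]))
})

test_that("evaluation statistics follow their definitions", {
  set.seed(8)
  lab <- sample_eye_coeffs(default_eye_model(), 20, seed = 8)
  # a perfect predictor
  ev <- evaluate_predictions(lab, lab)
  expect_equal(ev$summary$rmse_mean, 0)
  expect_equal(ev$summary$pass_rate, 1)
  # the all-zero predictor scores the mean true RMS (without tilt/tip)
  ev0 <- evaluate_predictions(matrix(0, 20, 44), lab)
  expect_equal(ev0$summary$rmse_mean,
               mean(apply(lab, 1, wavefront_rms, exclude = 1:2)))
  expect_equal(ev0$summary$est_rms_mean, 0)
  # residuals 0.05 and 0.10 against the 1/14 line: half pass
  true <- matrix(0, 2, 44)
  est <- true; est[1, 4] <- 0.05; est[2, 4] <- 0.10
  ev2 <- evaluate_predictions(est, true)
  expect_equal(ev2$summary$pass_rate, 0.5)
})

test_that("dataset generation is seeded, normalized and split as requested", {
  g <- geom_micro()
  ds <- generate_shwfs_dataset(c(train = 3, val = 2, test = 2),
                               geometry = g, input_side = 32, seed = 5)
  expect_equal(dim(ds$train$images), c(32, 32, 3))
  expect_equal(dim(ds$test$labels), c(2L, 44L))
  expect_equal(apply(ds$train$images, 3, max), rep(1, 3))
  ds2 <- generate_shwfs_dataset(c(train = 3, val = 2, test = 2),
                                geometry = g, input_side = 32, seed = 5)
  expect_identical(ds$train$labels, ds2$train$labels)
  expect_identical(ds$val$images, ds2$val$images)
  # splits are disjoint draws (different labels)
  expect_false(any(duplicated(rbind(ds$train$labels, ds$val$labels,
                                    ds$test$labels))))
})

test_that("limited-data and generalization harnesses compose correctly", {
  g <- geom_micro()
  ds <- generate_shwfs_dataset(c(train = 8, val = 4, test = 4),
                               geometry = g, input_side = 16, seed = 6)
  cfg <- cnn_config(input_side = 16, depths = c(1, 1, 1, 1),
                    widths = c(4, 6, 8, 10), dw_kernel = 3, patch = 2)
  out <- limited_data_experiment(ds, sizes = c(4, 8), cfg, epochs = 2,
                                 batch_size = 4, lr0 = 1e-4, seed = 2)
  expect_equal(out$size, c(4, 8))
  expect_true(all(is.finite(out$rmse_mean)))
  expect_error(limited_data_experiment(ds, sizes = 100, cfg), "pool")
  # generalization evaluates exactly like evaluate_cnn on the same draws
  m <- init_cnn(cfg, seed = 1)
  fit <- train_cnn(m, ds$train, epochs = 1, lr0 = 1e-4, seed = 1)
  tm <- turbulence_model(6)
  gt <- generalization_test(fit, tm, n = 3, geometry = g, input_side = 16,
                            seed = 9)
  ds_k <- generate_shwfs_dataset(c(test = 3), model = tm, geometry = g,
                                 input_side = 16, seed = 9,
                                 sampler = sample_kolmogorov_coeffs)
  expect_equal(gt$summary, evaluate_cnn(fit, ds_k$test)$summary)
  expect_equal(generalization_test(fit, tm, 0, g)$summary$n, 0L)
})
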