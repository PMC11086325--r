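# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Hartmannogram
#'
#' @param object A `hartmannogram`.
#' @param grid Overlay the sub-aperture grid (default `TRUE`).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hartmannogram <- function(object, grid = TRUE, ...) {
  ras <- object$intensity
  df <- tidyr::expand_grid(y = seq_len(nrow(ras)) - 1,
                           x = seq_len(ncol(ras)) - 1)
  df$intensity <- as.numeric(ras)[df$y + 1 + nrow(ras) * df$x]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "detector x (px)", y = "detector y (px)")
  if (grid) {
    ppsa <- object$geometry$pixels_per_subaperture
    lines <- seq(0, nrow(ras), by = ppsa) - 0.5
    p <- p + ggplot2::geom_hline(yintercept = lines, colour = "red",
                                 linewidth = 0.1, alpha = 0.5) +
      ggplot2::geom_vline(xintercept = lines, colour = "red",
                          linewidth = 0.1, alpha = 0.5)
  }
  p
}

#' Plot a wavefront map
#'
#' @param coeffs Zernike coefficients in waves.
#' @param samples Grid samples per side.
#' @return A ggplot of the wavefront in waves over the pupil.
#' @export
plot_wavefront <- function(coeffs, samples = 200) {
  wf <- wavefront_from_coeffs(coeffs, pupil_grid(samples))
  g <- wf$grid
  df <- tidyr::expand_grid(iy = seq_along(g$y), ix = seq_along(g$x))
  df$x <- g$x[df$ix]; df$y <- g$y[df$iy]
  df$w <- wf$values[cbind(df$iy, df$ix)]
  ggplot2::ggplot(df[!is.na(df$w), ],
                  ggplot2::aes(.data$x, .data$y, fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "waves") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (pupil radii)", y = "y (pupil radii)")
}

#' Plot training history
#'
#' @param object A `cnn_fit`.
#' @param ... Ignored.
#' @return A ggplot of train/validation loss per epoch (log scale).
#' @export
autoplot.cnn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h[!is.na(h$loss), ],
                  ggplot2::aes(.data$epoch, .data$loss,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "mean squared coefficient error")
}

#' Plot a dynamic-range sweep
#'
#' @param object A `dr_sweep` from [sweep_modes()].
#' @param ... Ignored.
#' @return A grouped bar chart of signed critical values per mode.
#' @export
autoplot.dr_sweep <- function(object, ...) {
  df <- as.data.frame(object)
  df$mode <- factor(paste0("Z", df$mode), levels = paste0("Z", sort(unique(df$mode))))
  ggplot2::ggplot(df, ggplot2::aes(.data$mode, .data$critical_value,
                                   fill = .data$reconstructor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(y = "critical amplitude (waves)")
}
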