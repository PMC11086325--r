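# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained network fit
#'
#' @param x A `cnn_fit`.
#' @param ... Ignored.
#' @return The per-epoch history tibble.
#' @export
tidy.cnn_fit <- function(x, ...) x$history

#' @rdname tidy.cnn_fit
#' @return `glance()`: one row with epochs, final/best losses and final lr.
#' @export
glance.cnn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    train_loss = utils::tail(h$train_loss, 1),
    best_val_loss = if (all(is.na(h$val_loss))) NA_real_ else
      min(h$val_loss, na.rm = TRUE),
    final_lr = utils::tail(h$lr, 1))
}

#' Tidy an evaluation
#'
#' @param x A `shwfs_eval`.
#' @param ... Ignored.
#' @return Per-sample tibble (`tidy`) or the one-row summary (`glance`).
#' @export
tidy.shwfs_eval <- function(x, ...) x$samples

#' @rdname tidy.shwfs_eval
#' @export
glance.shwfs_eval <- function(x, ...) x$summary

#' Tidy a dynamic-range sweep
#'
#' @param x A `dr_sweep`.
#' @param ... Ignored.
#' @return The sweep tibble (`tidy`); `glance` summarises the improvement
#'   range of each non-baseline reconstructor.
#' @export
tidy.dr_sweep <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.dr_sweep
#' @export
glance.dr_sweep <- function(x, ...) {
  df <- tibble::as_tibble(x)
  base <- df$reconstructor[1]
  df <- df[df$reconstructor != base & !df$unbounded, ]
  if (nrow(df) == 0) {
    return(tibble::tibble(reconstructor = character(),
                          min_improvement = numeric(),
                          max_improvement = numeric()))
  }
  dplyr::summarise(dplyr::group_by(df, .data$reconstructor),
                   min_improvement = min(.data$improvement),
                   max_improvement = max(.data$improvement),
                   .groups = "drop")
}
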