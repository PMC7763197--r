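# ggplot2 views of the package's result objects.

#' @export
autoplot.mirloc_fit <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                              names_to = "split", values_to = "loss")
  long <- long[is.finite(long$loss), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mirloc_cv <- function(object, ...) {
  long <- tidy(object)
  means <- dplyr::group_by(long, .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = means, colour = "red", shape = 3, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Cross-validation metrics (folds and mean)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a positional-encoding matrix
#'
#' @param pe A matrix from [positional_matrix()].
#' @param max_positions Number of leading positions to show.
#' @return A ggplot object.
#' @export
plot_positional_matrix <- function(pe, max_positions = 64L) {
  pe <- pe[seq_len(min(nrow(pe), max_positions)), , drop = FALSE]
  df <- tidyr::expand_grid(position = seq_len(nrow(pe)) - 1L,
                           dimension = seq_len(ncol(pe)))
  df$value <- as.vector(pe)[(df$dimension - 1L) * nrow(pe) + df$position + 1L]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dimension, y = .data$position,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = "Sinusoidal positional encoding",
                  fill = "PE") +
    ggplot2::theme_minimal()
}
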