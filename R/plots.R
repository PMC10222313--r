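#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_text
#'   scale_fill_gradient labs theme_minimal facet_wrap
NULL

#' Plot an encoded image
#'
#' Grayscale tile plot of the pixel matrix, rows drawn top-down so channel
#' (or channel-block) order matches the matrix layout.
#'
#' @param object an `emg_image`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.emg_image <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$value <- as.vector(t(object$pixels))[
    (df$row - 1) * ncol(object$pixels) + df$col]
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    labs(title = sprintf("%s image (%d x %d), gesture %s", object$encoder,
                         nrow(object$pixels), ncol(object$pixels),
                         object$label),
         x = NULL, y = NULL, fill = "gray") +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' Heatmap of counts with true gesture on the x axis and predicted gesture
#' on the y axis; set `transpose = TRUE` to swap the axes.
#'
#' @param object an `emg_eval`.
#' @param transpose swap the axes.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.emg_eval <- function(object, transpose = FALSE, ...) {
  cm <- object$confusion
  df <- tidyr::expand_grid(truth = seq_len(nrow(cm)) - 1L,
                           predicted = seq_len(ncol(cm)) - 1L)
  df$count <- as.integer(cm)[df$truth * nrow(cm) + df$predicted + 1L]
  if (transpose) names(df)[1:2] <- c("predicted", "truth")
  ggplot(df, aes(x = .data$truth, y = .data$predicted, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), color = "grey30", size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "true gesture", y = "predicted gesture",
         title = sprintf("average accuracy %.1f%%",
                         round_half_up(object$average_accuracy, 1))) +
    theme_minimal()
}

#' Plot training history
#'
#' @param object an `emg_cnn_fit`.
#' @param ... unused.
#' @return A ggplot of per-epoch loss and training accuracy.
#' @export
autoplot.emg_cnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL) +
    theme_minimal()
}

#' @export
ggplot2::autoplot
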