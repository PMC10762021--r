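#' Tidy the training history of a fitted model
#'
#' @param x A `cnv_model`.
#' @param ... Unused.
#' @return The per-epoch loss trace as a tibble (`epoch`, `loss`, `lr`);
#'   empty for an untrained model.
#' @export
tidy.cnv_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), loss = numeric(), lr = numeric()))
  }
  x$history
}

#' One-row summary of a model
#'
#' @param x A `cnv_model`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, parameter count, epochs trained,
#'   final loss.
#' @export
glance.cnv_model <- function(x, ...) {
  n_par <- sum(vapply(flatten_params(x$params), length, integer(1)))
  tibble::tibble(
    H = x$config$H, L = x$config$L, heads = x$config$heads,
    max_len = x$config$max_len, n_parameters = n_par,
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)])
}

#' Plot a training loss trace
#'
#' @param object A trained `cnv_model`.
#' @param ... Unused.
#' @return A ggplot of loss against epoch.
#' @export
autoplot.cnv_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy loss") +
    ggplot2::theme_minimal()
}

#' Plot per-class precision/recall/F1 of an evaluation
#'
#' @param object A `cnv_metrics` object.
#' @param ... Unused.
#' @return A ggplot bar chart of the per-class metric suite.
#' @export
autoplot.cnv_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class,
                            cols = c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
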