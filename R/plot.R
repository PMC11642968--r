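# ggplot2 presentation methods for result objects.

#' @export
autoplot.perio_confusion <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(unclass(object))))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted class", y = "True class", fill = "Count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.perio_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_class, c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$class), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Class", y = NULL, fill = NULL,
                  subtitle = paste0("accuracy = ", round(object$accuracy, 3))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.perio_attribution <- function(object, top_n = 15, ...) {
  df <- dplyr::slice_max(tibble::as_tibble(object), abs(.data$weight),
                         n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight,
                                   y = stats::reorder(.data$token, .data$weight),
                                   fill = .data$weight > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Surrogate weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.perio_text_model <- function(object, ...) {
  stopifnot(!is.null(object$history))
  df <- tidyr::pivot_longer(object$history,
                            c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "Epoch", y = "Weighted cross-entropy", color = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of a grid-search report
#'
#' @param grid A `perio_grid` from [grid_search()].
#' @return A ggplot object.
#' @export
plot_grid_search <- function(grid) {
  ggplot2::ggplot(grid$grid, ggplot2::aes(x = .data$hidden1, y = .data$hidden2,
                                          fill = .data$val_accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Hidden layer 1 units", y = "Hidden layer 2 units",
                  fill = "Val. accuracy") +
    ggplot2::theme_minimal()
}
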