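# ggplot2 views of the main result types. Each autoplot returns a ggplot
# the caller can restyle.

#' @describeIn run_experiment Heat map of the averaged confusion matrix.
#' @param object A `painflow_eval`.
#' @export
autoplot.painflow_eval <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(object$mean_confusion)))
  names(df) <- c("true", "predicted", "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate)),
                       color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "grey20", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "rate",
                  title = sprintf("Mean confusion over %d runs (accuracy %.3f)",
                                  nrow(object$per_run), object$mean_accuracy))
}

#' @describeIn sweep_hyperparameter Accuracy (with +/- 1 sd ribbon) against
#'   the swept value.
#' @param object A `painflow_sweep`.
#' @param ... Unused.
#' @export
autoplot.painflow_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                       y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$parameter[1], y = "mean accuracy",
                  title = sprintf("Accuracy against %s", object$parameter[1]))
}

#' @describeIn horn_schunck_flow Downsampled quiver plot of the flow field.
#' @param object A `flow_field`.
#' @param stride Arrow spacing in pixels (default 4).
#' @param ... Unused.
#' @export
autoplot.flow_field <- function(object, stride = 4L, ...) {
  n <- nrow(object$ux)
  m <- ncol(object$ux)
  ri <- seq(1L, n, by = stride)
  ci <- seq(1L, m, by = stride)
  df <- expand.grid(y = ri, x = ci)
  df$ux <- object$ux[cbind(df$y, df$x)]
  df$uy <- object$uy[cbind(df$y, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + .data$ux,
                                       yend = .data$y + .data$uy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "pt"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Optical flow field")
}

#' @describeIn splsa_train Per-class word-probability profiles.
#' @param object An `splsa` model.
#' @export
autoplot.splsa <- function(object, ...) {
  df <- tidy(object)
  df$word_index <- as.integer(sub("^w", "", df$word))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$word_index,
                                   y = .data$probability)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~class, ncol = 1) +
    ggplot2::labs(x = "visual word", y = "p(word | class topic)",
                  title = "Word-topic distributions")
}
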