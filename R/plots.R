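# ggplot2 displays of fitted objects.

#' Scatter plot of common factor scores
#'
#' Plots the first two common factor score columns (clustering fits are
#' colored by membership, with centroids marked).
#'
#' @param object A fitted `fe_fit` object with at least two factors.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fe_fit <- function(object, ...) {
  if (object$r < 2) abort("Score plot needs at least two factors.")
  df <- augment(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$F1, y = .data$F2))
  if (!is.null(object$cluster)) {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(colour = .data$.cluster), alpha = 0.8) +
      ggplot2::geom_point(
        data = tibble::tibble(F1 = object$centroids[, 1],
                              F2 = object$centroids[, 2],
                              .cluster = factor(seq_len(nrow(object$centroids)))),
        ggplot2::aes(colour = .data$.cluster), shape = 4, size = 4, stroke = 2
      ) +
      ggplot2::labs(colour = "cluster")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::labs(x = "Factor 1 score", y = "Factor 2 score") +
    ggplot2::theme_minimal()
}

#' Loading heatmap
#'
#' @param fit A fitted `fe_fit` object.
#' @return A ggplot object: variables by factors, tile fill = loading.
#' @export
plot_loadings <- function(fit) {
  df <- tidy(fit, matrix = "loadings")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor,
                                   y = factor(.data$variable, rev(unique(.data$variable))),
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1) * max(abs(df$loading))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' Loss trajectory of the best start
#'
#' @param fit A fitted `fe_fit` object.
#' @return A ggplot object of loss against iteration.
#' @export
plot_loss_path <- function(fit) {
  df <- tibble::tibble(iteration = seq_along(fit$loss_path), loss = fit$loss_path)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::theme_minimal()
}
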