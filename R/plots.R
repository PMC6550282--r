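# ggplot2 display methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' @param object A `cnn_fit` or `unet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cnn_fit
#' @export
autoplot.cnn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss, colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "cross-entropy (nats)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cnn_fit
#' @method autoplot unet_fit
#' @export
autoplot.unet_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "pixel-wise cross-entropy (nats)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cnn_fit
#' @method autoplot ssgan_fit
#' @export
autoplot.ssgan_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("test_accuracy", "test_f1"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value, colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a label-efficiency curve
#'
#' Median test accuracy (over seeds) against labels per class, on a log2
#' label axis to expose the asymptotic flattening.
#'
#' @param object A [label_efficiency_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot label_efficiency
#' @export
autoplot.label_efficiency <- function(object, ...) {
  med <- dplyr::summarise(dplyr::group_by(object, .data$labels_per_class),
                          test_accuracy = stats::median(.data$test_accuracy))
  ggplot2::ggplot(object, ggplot2::aes(.data$labels_per_class, .data$test_accuracy)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = med) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "labels per class", y = "test accuracy") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for an evaluation report
#'
#' @param object An [eval_report()].
#' @param ... Unused.
#' @return A ggplot of the row-normalised confusion matrix.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    true = rep(0:(object$k - 1L), times = object$k),
    pred = rep(0:(object$k - 1L), each = object$k),
    prop = as.vector(cm)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$true, fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prop)), size = 3) +
    ggplot2::scale_y_reverse(breaks = 0:(object$k - 1L)) +
    ggplot2::scale_x_continuous(breaks = 0:(object$k - 1L)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "row prop.") +
    ggplot2::theme_minimal()
}

#' Display a phantom sample or a generated-sample grid
#'
#' @param x A `phantom_sample` (image plus masks) or a `(H, W, 1, N)` array
#'   of generated images in `[0, 1]`.
#' @param ncol Grid columns for arrays.
#' @return A ggplot raster.
#' @export
plot_images <- function(x, ncol = 4L) {
  if (inherits(x, "phantom_sample")) {
    panels <- list(image = x$image, fov_mask = x$fov_mask)
    if (!is.null(x$lv_mask)) panels$lv_mask <- x$lv_mask
    df <- dplyr::bind_rows(lapply(names(panels), function(nm) {
      m <- panels[[nm]]
      tibble::tibble(panel = nm,
                     row = rep(seq_len(nrow(m)), times = ncol(m)),
                     col = rep(seq_len(ncol(m)), each = nrow(m)),
                     value = as.vector(m))
    }))
    df$panel <- factor(df$panel, levels = names(panels))
  } else {
    n <- dim(x)[4]
    df <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      m <- x[, , 1, i]
      tibble::tibble(panel = sprintf("sample %d", i),
                     row = rep(seq_len(nrow(m)), times = ncol(m)),
                     col = rep(seq_len(ncol(m)), each = nrow(m)),
                     value = as.vector(m))
    }))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::facet_wrap(~panel, ncol = ncol) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() + ggplot2::theme(legend.position = "none")
}
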