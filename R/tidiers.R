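# broom-style tidiers for fitted objects and evaluation reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report into per-class rows
#'
#' @param x An [eval_report()].
#' @param ... Unused.
#' @return Tibble with `class`, `n`, `accuracy`.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  counts <- rowSums(x$confusion_counts)
  tibble::tibble(class = 0:(x$k - 1L), n = as.integer(counts),
                 accuracy = x$per_class_accuracy)
}

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, f1 = x$f1,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 ci_low = x$ci[["low"]], ci_high = x$ci[["high"]],
                 ci_half_width = x$ci_half_width, level = x$level, n = x$n)
}

#' Tidy training histories
#'
#' `tidy()` returns the per-epoch history; `glance()` a one-row summary of
#' the epoch the fit retained (best validation loss when a validation split
#' was present).
#'
#' @param x A `cnn_fit`, `unet_fit`, `transfer_fit` or `ssgan_fit`.
#' @param ... Unused.
#' @method tidy cnn_fit
#' @export
tidy.cnn_fit <- function(x, ...) x$history

#' @rdname tidy.cnn_fit
#' @method glance cnn_fit
#' @export
glance.cnn_fit <- function(x, ...) {
  h <- x$history
  best <- if (all(is.na(h$val_loss))) nrow(h) else which.min(h$val_loss)
  tibble::tibble(epochs = nrow(h), best_epoch = best,
                 train_loss = h$train_loss[best], train_acc = h$train_acc[best],
                 val_loss = h$val_loss[best], val_acc = h$val_acc[best])
}

#' @rdname tidy.cnn_fit
#' @method tidy unet_fit
#' @export
tidy.unet_fit <- function(x, ...) x$history

#' @rdname tidy.cnn_fit
#' @method glance unet_fit
#' @export
glance.unet_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), final_loss = h$loss[nrow(h)])
}

#' @rdname tidy.cnn_fit
#' @method tidy transfer_fit
#' @export
tidy.transfer_fit <- function(x, ...) {
  dplyr::bind_rows(dplyr::mutate(x$stage1, stage = 1L),
                   dplyr::mutate(x$stage2, stage = 2L))
}

#' @rdname tidy.cnn_fit
#' @method tidy ssgan_fit
#' @export
tidy.ssgan_fit <- function(x, ...) x$history

#' @rdname tidy.cnn_fit
#' @method glance ssgan_fit
#' @export
glance.ssgan_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), iters_per_epoch = x$iters_per_epoch,
                 test_accuracy = h$test_accuracy[nrow(h)],
                 test_f1 = h$test_f1[nrow(h)])
}
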