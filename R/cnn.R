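# VGG-style supervised classifier: resolution-dependent design rules,
# Adam training with per-epoch learning-rate decay and patience-2 early
# stopping, two-stage transfer learning, ensembling, and the resolution
# study harness.

#' CNN configuration and the resolution-dependent design rules
#'
#' `default_config_for_resolution()` encodes the three printed design rules:
#' 3x3 filters, same padding, stride 1 and 2x2 pooling everywhere; max
#' pooling at resolutions of 60x80 and above, average pooling below; 7x7
#' filters for the first two convolution layers at 240x320 and larger; and
#' average pooling whenever the input is mask-preprocessed
#' (`masked_input = TRUE`). Block depth scales with `log2` of the smaller
#' input dimension, filters doubling per block.
#'
#' @param h,w Input resolution in pixels.
#' @param n_classes Number of output classes.
#' @param masked_input Set when the classifier consumes mask-preprocessed
#'   images; switches pooling to average.
#' @param base_filters First-block filter count (doubles per block, capped).
#' @return A `cnn_config`.
#' @export
default_config_for_resolution <- function(h, w, n_classes, masked_input = FALSE,
                                          base_filters = 8L) {
  n_blocks <- max(2L, min(5L, floor(log2(min(h, w))) - 2L))
  filters <- pmin(base_filters * 2^(seq_len(n_blocks) - 1L), 64L)
  big <- min(h, w) >= 240
  blocks <- lapply(seq_len(n_blocks), function(i) {
    if (big && i <= 2) {
      list(n_convs = 1L, filters = filters[i], filter_size = 7L)
    } else {
      list(n_convs = 2L, filters = filters[i], filter_size = 3L)
    }
  })
  pooling <- if (masked_input || min(h, w) < 60) "average" else "max"
  cnn_config(h, w, conv_blocks = blocks, pooling = pooling, n_classes = n_classes)
}

#' @rdname default_config_for_resolution
#' @param input_h,input_w Input resolution in pixels.
#' @param conv_blocks List of blocks `list(n_convs, filters, filter_size)`.
#' @param pooling `"max"` or `"average"` (2x2 window, fixed).
#' @param fc_sizes Fully-connected layer widths.
#' @param dropout_rate,l2_strength Head regularisation (defaults 0.4 / 0.03).
#' @export
cnn_config <- function(input_h, input_w, conv_blocks, pooling = c("max", "average"),
                       fc_sizes = 64L, dropout_rate = 0.4, l2_strength = 0.03,
                       n_classes = 2L) {
  pooling <- match.arg(pooling)
  for (b in conv_blocks) {
    if (b$filter_size %% 2 == 0) stop("filter sizes must be odd", call. = FALSE)
  }
  structure(list(input_h = as.integer(input_h), input_w = as.integer(input_w),
                 conv_blocks = conv_blocks, pooling = pooling,
                 fc_sizes = as.integer(fc_sizes), dropout_rate = dropout_rate,
                 l2_strength = l2_strength, n_classes = as.integer(n_classes)),
            class = "cnn_config")
}

#' Build a CNN classifier from a configuration
#'
#' Convolution trunk (conv + batch norm + ReLU per layer, 2x2 pooling per
#' block) followed by fully-connected layers with batch norm, ReLU, dropout
#' and L2 weight decay, and a final softmax over `n_classes`.
#'
#' @param config A `cnn_config`.
#' @param seed Optional seed for weight initialisation.
#' @return A `cnn_model` (mutable; training updates it in place).
#' @export
build_cnn <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cnn_config"))
  if (!is.null(seed)) set.seed(seed)
  trunk <- list()
  in_ch <- 1L
  h <- config$input_h; w <- config$input_w
  for (b in config$conv_blocks) {
    for (j in seq_len(b$n_convs)) {
      trunk <- c(trunk, list(nn_conv(in_ch, b$filters, b$filter_size),
                             nn_bn(b$filters), nn_act("relu")))
      in_ch <- b$filters
    }
    trunk <- c(trunk, list(nn_pool(config$pooling)))
    h <- h %/% 2L; w <- w %/% 2L
  }
  head <- list(nn_flatten())
  in_dim <- h * w * in_ch
  for (fs in config$fc_sizes) {
    head <- c(head, list(nn_dense(in_dim, fs, l2 = config$l2_strength, init = "xavier"),
                         nn_bn(fs, spatial = FALSE), nn_act("relu"),
                         nn_dropout(config$dropout_rate)))
    in_dim <- fs
  }
  head <- c(head, list(nn_dense(in_dim, config$n_classes,
                                l2 = config$l2_strength, init = "xavier")))
  structure(list(config = config, trunk = trunk, head = head), class = "cnn_model")
}

cnn_layers <- function(model) c(model$trunk, model$head)

cnn_forward <- function(model, x, training = FALSE) {
  x <- run_layers(model$trunk, x, training)
  run_layers(model$head, x, training)
}

cnn_backward <- function(model, dy) {
  dy <- run_layers_bwd(model$head, dy)
  run_layers_bwd(model$trunk, dy)
}

#' Class probabilities from a CNN
#'
#' @param object A `cnn_model`.
#' @param images List of matrices or an `(H, W, 1, N)` array.
#' @param ... Unused.
#' @return An `N x K` matrix of class probabilities (rows sum to 1; columns
#'   are 0-based classes `0..K-1` in order).
#' @export
predict.cnn_model <- function(object, images, ...) {
  x <- if (is.list(images)) stack_images(images) else images
  t(softmax_cols(cnn_forward(object, x, training = FALSE)))
}

#' Classifier training schedule
#'
#' Defaults follow the supervised recipe: Adam, initial learning rate 0.02
#' with per-epoch decay 0.85, early stopping once validation loss stops
#' (strictly) decreasing for two consecutive epochs, and augmentation of
#' training batches with up to 10 degrees rotation and 10% height/width
#' shifts.
#'
#' @param lr0,decay,max_epochs,patience,batch_size,seed Schedule fields.
#' @param max_rotation,max_shift Augmentation limits (0 disables).
#' @return A `train_schedule`.
#' @export
train_schedule <- function(lr0 = 0.02, decay = 0.85, max_epochs = 30L, patience = 2L,
                           batch_size = 32L, max_rotation = 10, max_shift = 0.1,
                           seed = 1L) {
  if (patience < 1) stop("patience must be >= 1", call. = FALSE)
  structure(list(lr0 = lr0, decay = decay, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), batch_size = as.integer(batch_size),
                 max_rotation = max_rotation, max_shift = max_shift,
                 seed = as.integer(seed)),
            class = "train_schedule")
}

#' Learning rate at a (0-based) epoch
#'
#' @param schedule A schedule with `lr0` and `decay`.
#' @param epoch 0-based epoch index.
#' @return `lr0 * decay^epoch`.
#' @export
lr_at_epoch <- function(schedule, epoch) schedule$lr0 * schedule$decay^epoch

# Early stopping bookkeeping: given the validation losses seen so far,
# returns the 1-based epoch training should stop after (or NA), and the
# epoch whose weights should be kept. "Decreasing" means a strict decrease
# of validation loss against the running best.
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf; best_at <- NA_integer_; streak <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_at <- e; streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= patience) return(list(stop_after = e, best = best_at))
    }
  }
  list(stop_after = NA_integer_, best = best_at)
}

#' Train a CNN classifier
#'
#' Minimises categorical cross-entropy with Adam; the learning rate decays
#' per epoch, augmentation is applied to training batches only, and training
#' stops at `max_epochs` or once validation loss has failed to improve for
#' `patience` consecutive epochs, restoring the weights of the
#' best-validation-loss epoch. Seeded and reproducible on one thread.
#'
#' @param model A `cnn_model` (updated in place).
#' @param data Tibble with an image list-column, a label column (0-based)
#'   and a `split` column containing `"train"` and `"val"` rows.
#' @param schedule A [train_schedule()].
#' @param label_col,image_col Column names.
#' @return A `cnn_fit` with the model and per-epoch `history` tibble.
#' @export
train_cnn <- function(model, data, schedule = train_schedule(),
                      label_col = "view_label", image_col = "image") {
  stopifnot(inherits(model, "cnn_model"))
  tr <- data[data$split == "train" & !is.na(data$split), ]
  va <- data[data$split == "val" & !is.na(data$split), ]
  if (nrow(tr) == 0) stop("empty training split", call. = FALSE)
  x_tr <- tr[[image_col]]; y_tr <- tr[[label_col]]
  has_val <- nrow(va) > 0
  if (has_val) {
    x_va <- stack_images(va[[image_col]])
    y_va <- va[[label_col]]
  }
  set.seed(schedule$seed)
  layers <- cnn_layers(model)
  n <- length(x_tr)
  step <- 0L
  hist <- list()
  val_losses <- numeric(0)
  best_snap <- NULL
  for (ep in seq_len(schedule$max_epochs)) {
    lr <- lr_at_epoch(schedule, ep - 1L)
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L; nb <- 0L
    for (b0 in seq(1L, n, by = schedule$batch_size)) {
      idx <- ord[b0:min(b0 + schedule$batch_size - 1L, n)]
      imgs <- x_tr[idx]
      if (schedule$max_rotation > 0 || schedule$max_shift > 0) {
        imgs <- lapply(imgs, augment, max_rotation = schedule$max_rotation,
                       max_shift = schedule$max_shift)
      }
      x <- stack_images(imgs)
      logits <- cnn_forward(model, x, training = TRUE)
      probs <- softmax_cols(logits)
      ce <- softmax_ce(probs, y_tr[idx])
      cnn_backward(model, ce$dlogits)
      step <- step + 1L
      adam_step(layers, lr, step)
      ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
      ep_correct <- ep_correct + sum(max.col(t(probs)) - 1L == y_tr[idx])
    }
    row <- tibble::tibble(epoch = ep, lr = lr,
                          train_loss = ep_loss / nb, train_acc = ep_correct / n,
                          val_loss = NA_real_, val_acc = NA_real_,
                          seconds = proc.time()[["elapsed"]] - t0)
    if (has_val) {
      probs <- softmax_cols(cnn_forward(model, x_va, training = FALSE))
      row$val_loss <- softmax_ce(probs, y_va)$loss
      row$val_acc <- mean(max.col(t(probs)) - 1L == y_va)
      val_losses <- c(val_losses, row$val_loss)
      es <- early_stop_epoch(val_losses, schedule$patience)
      if (!is.na(es$best) && es$best == ep) best_snap <- snapshot_params(layers)
      hist[[ep]] <- row
      if (!is.na(es$stop_after)) break
    } else {
      hist[[ep]] <- row
    }
  }
  if (has_val && !is.null(best_snap)) restore_params(layers, best_snap)
  structure(list(model = model, history = dplyr::bind_rows(hist), schedule = schedule),
            class = "cnn_fit")
}

#' Two-stage transfer learning from a trained classifier
#'
#' The source model's convolution trunk is kept and a fresh fully-connected
#' head (Xavier-uniform initialisation, L2 0.03, dropout 0.4 by default) is
#' attached for the target task. Stage 1 freezes the convolution weights and
#' trains only the head; stage 2 freezes the head and fine-tunes the
#' convolution layers. The freezes are exact: stage 1 leaves every trunk
#' parameter bit-identical, stage 2 every head parameter.
#'
#' @param source A trained `cnn_model` (it is not modified).
#' @param data Target-task tibble as for [train_cnn()].
#' @param stage1,stage2 [train_schedule()]s; canonical choices are
#'   `lr0 = 0.025, decay = 0.85, max_epochs = 20` for stage 1 and
#'   `lr0 = 0.001, decay = 0.9` for stage 2.
#' @param n_classes Target-task class count (2 for LVH).
#' @param label_col,image_col Column names in `data`.
#' @param seed Seed for the new head's initialisation.
#' @return A `transfer_fit` with the adapted model and both stage histories.
#' @export
two_stage_transfer <- function(source, data,
                               stage1 = train_schedule(lr0 = 0.025, decay = 0.85,
                                                       max_epochs = 20L),
                               stage2 = train_schedule(lr0 = 0.001, decay = 0.9,
                                                       max_epochs = 20L),
                               n_classes = 2L, label_col = "lvh_label",
                               image_col = "image", seed = 1L) {
  stopifnot(inherits(source, "cnn_model"))
  cfg <- source$config
  cfg$n_classes <- as.integer(n_classes)
  set.seed(seed)
  trunk <- lapply(source$trunk, clone_layer)
  # fresh head, Xavier-uniform
  h <- cfg$input_h; w <- cfg$input_w
  for (b in cfg$conv_blocks) { h <- h %/% 2L; w <- w %/% 2L }
  in_ch <- cfg$conv_blocks[[length(cfg$conv_blocks)]]$filters
  head <- list(nn_flatten())
  in_dim <- h * w * in_ch
  for (fs in cfg$fc_sizes) {
    head <- c(head, list(nn_dense(in_dim, fs, l2 = cfg$l2_strength, init = "xavier"),
                         nn_bn(fs, spatial = FALSE), nn_act("relu"),
                         nn_dropout(cfg$dropout_rate)))
    in_dim <- fs
  }
  head <- c(head, list(nn_dense(in_dim, cfg$n_classes, l2 = cfg$l2_strength,
                                init = "xavier")))
  model <- structure(list(config = cfg, trunk = trunk, head = head), class = "cnn_model")

  for (l in model$trunk) l$trainable <- FALSE
  fit1 <- train_cnn(model, data, stage1, label_col = label_col, image_col = image_col)
  trunk_after_stage1 <- snapshot_params(model$trunk)
  head_after_stage1 <- snapshot_params(model$head)
  for (l in model$trunk) l$trainable <- TRUE
  for (l in model$head) l$trainable <- FALSE
  fit2 <- train_cnn(model, data, stage2, label_col = label_col, image_col = image_col)
  for (l in model$head) l$trainable <- TRUE
  structure(list(model = model, stage1 = fit1$history, stage2 = fit2$history,
                 trunk_after_stage1 = trunk_after_stage1,
                 head_after_stage1 = head_after_stage1),
            class = "transfer_fit")
}

#' Average the predictions of an ensemble of classifiers
#'
#' Arithmetic mean of the per-model probability matrices; rows still sum
#' to 1, so the average stays on the probability simplex.
#'
#' @param models List of `cnn_model`s (a single model is allowed).
#' @param images List of matrices or an `(H, W, 1, N)` array.
#' @return An `N x K` probability matrix.
#' @export
ensemble_predict <- function(models, images) {
  if (inherits(models, "cnn_model")) models <- list(models)
  x <- if (is.list(images) && !inherits(images[[1]], "cnn_model")) images else images
  probs <- lapply(models, function(m) predict(m, x))
  Reduce(`+`, probs) / length(probs)
}

#' Resolution study: accuracy and epoch time across input resolutions
#'
#' Trains one default-configuration model per resolution on identically
#' split data (images are resized per resolution with [resize_nearest()])
#' and reports validation accuracy and measured seconds per epoch.
#'
#' @param resolutions List of `c(h, w)` pairs.
#' @param data Tibble with image list-column, label column and `split`.
#' @param schedule A [train_schedule()] applied at every resolution.
#' @param label_col,image_col Column names.
#' @return A tibble with one row per resolution: `height`, `width`,
#'   `resolution`, `val_accuracy`, `seconds_per_epoch`, `epochs`.
#' @export
resolution_study <- function(resolutions, data, schedule = train_schedule(),
                             label_col = "view_label", image_col = "image") {
  n_classes <- length(unique(data[[label_col]]))
  rows <- lapply(resolutions, function(res) {
    h <- res[1]; w <- res[2]
    d <- data
    d[[image_col]] <- lapply(d[[image_col]], resize_nearest, target_h = h, target_w = w)
    cfg <- default_config_for_resolution(h, w, n_classes)
    model <- build_cnn(cfg, seed = schedule$seed)
    fit <- train_cnn(model, d, schedule, label_col = label_col, image_col = image_col)
    hh <- fit$history
    tibble::tibble(height = h, width = w, resolution = paste0(h, "x", w),
                   val_accuracy = hh$val_acc[which.min(hh$val_loss)],
                   seconds_per_epoch = mean(hh$seconds), epochs = nrow(hh))
  })
  dplyr::bind_rows(rows)
}
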