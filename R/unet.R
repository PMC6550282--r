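# Modified U-Net segmenter for field-of-view and left-ventricle masks.
#
# The encoder stacks `depth` levels of two 3x3 convolutions (batch norm +
# ReLU) followed by 2x2 max pooling, with filter counts doubling per level
# from `base_filters` but capped below 1024 (`max_filters`); the decoder
# mirrors it with stride-2 transposed convolutions and skip concatenations,
# and dropout sits at the end of the bottleneck, before the first
# up-sampling convolution. A 1x1 convolution and per-pixel softmax produce
# the segmentation map.

#' U-Net configuration
#'
#' @param input_h,input_w Input size in pixels; must be divisible by
#'   `2^depth` so pooling and upsampling mirror exactly.
#' @param base_filters Filters at the first encoder level; doubled per level.
#' @param depth Number of down/up levels.
#' @param max_filters Cap on filters per level (below 1024; the widest
#'   original U-Net stage is deliberately removed).
#' @param dropout_rate Dropout before the first up-sampling convolution.
#' @param n_out_classes Output channels (2 for mask/background).
#' @return A `unet_config` list.
#' @export
unet_config <- function(input_h, input_w, base_filters = 16L, depth = 3L,
                        max_filters = 512L, dropout_rate = 0.5, n_out_classes = 2L) {
  if (input_h %% 2^depth != 0 || input_w %% 2^depth != 0) {
    stop("input dimensions must be divisible by 2^depth", call. = FALSE)
  }
  if (max_filters >= 1024) stop("max_filters must be below 1024", call. = FALSE)
  structure(list(input_h = as.integer(input_h), input_w = as.integer(input_w),
                 base_filters = as.integer(base_filters), depth = as.integer(depth),
                 max_filters = as.integer(max_filters), dropout_rate = dropout_rate,
                 n_out_classes = as.integer(n_out_classes)),
            class = "unet_config")
}

conv_bn_relu <- function(in_ch, out_ch) {
  list(nn_conv(in_ch, out_ch, 3L), nn_bn(out_ch), nn_act("relu"))
}

#' Build a modified U-Net segmentation model
#'
#' @param config A [unet_config()].
#' @param seed Optional seed for weight initialisation.
#' @return A `unet_model` object (mutable; training updates it in place).
#' @export
build_unet <- function(config, seed = NULL) {
  stopifnot(inherits(config, "unet_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$depth
  filters <- pmin(config$base_filters * 2^(seq_len(d) - 1L), config$max_filters)
  bottleneck_f <- min(config$base_filters * 2^d, config$max_filters)

  enc <- vector("list", d)
  in_ch <- 1L
  for (i in seq_len(d)) {
    enc[[i]] <- c(conv_bn_relu(in_ch, filters[i]), conv_bn_relu(filters[i], filters[i]))
    in_ch <- filters[i]
  }
  pools <- lapply(seq_len(d), function(i) nn_pool("max"))
  bottleneck <- c(conv_bn_relu(filters[d], bottleneck_f),
                  conv_bn_relu(bottleneck_f, bottleneck_f))
  drop <- nn_dropout(config$dropout_rate)

  ups <- vector("list", d)
  dec <- vector("list", d)
  in_ch <- bottleneck_f
  for (i in rev(seq_len(d))) {
    ups[[i]] <- nn_convT(in_ch, filters[i])
    dec[[i]] <- c(conv_bn_relu(2L * filters[i], filters[i]),
                  conv_bn_relu(filters[i], filters[i]))
    in_ch <- filters[i]
  }
  final <- nn_conv(filters[1], config$n_out_classes, k = 1L, pad = 0L)

  structure(list(config = config, filters = filters, bottleneck_filters = bottleneck_f,
                 enc = enc, pools = pools, bottleneck = bottleneck, dropout = drop,
                 ups = ups, dec = dec, final = final),
            class = "unet_model")
}

unet_layers <- function(model) {
  c(unlist(model$enc, recursive = FALSE), model$pools,
    model$bottleneck, list(model$dropout), model$ups,
    unlist(model$dec, recursive = FALSE), list(model$final))
}

run_layers <- function(layers, x, training) {
  for (l in layers) x <- layer_forward(l, x, training)
  x
}

run_layers_bwd <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

# Forward to logits (H, W, n_out, N); caches live in the layer envs.
unet_forward <- function(model, x, training = FALSE) {
  d <- model$config$depth
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    x <- run_layers(model$enc[[i]], x, training)
    skips[[i]] <- x
    x <- layer_forward(model$pools[[i]], x, training)
  }
  x <- run_layers(model$bottleneck, x, training)
  x <- layer_forward(model$dropout, x, training)
  for (i in rev(seq_len(d))) {
    up <- layer_forward(model$ups[[i]], x, training)
    x <- abind4(skips[[i]], up)
    x <- run_layers(model$dec[[i]], x, training)
  }
  layer_forward(model$final, x, training)
}

unet_backward <- function(model, dy) {
  d <- model$config$depth
  dy <- layer_backward(model$final, dy)
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    dy <- run_layers_bwd(model$dec[[i]], dy)
    nf <- model$filters[i]
    dskips[[i]] <- dy[, , seq_len(nf), , drop = FALSE]
    dup <- dy[, , nf + seq_len(nf), , drop = FALSE]
    dy <- layer_backward(model$ups[[i]], dup)
  }
  dy <- layer_backward(model$dropout, dy)
  dy <- run_layers_bwd(model$bottleneck, dy)
  for (i in rev(seq_len(d))) {
    dy <- layer_backward(model$pools[[i]], dy)
    dy <- dy + dskips[[i]]
    dy <- run_layers_bwd(model$enc[[i]], dy)
  }
  dy
}

# concatenate two (H, W, C, N) arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# channel c of an (H, W, C, N) array as an (H, W, N) array (no dim dropping
# surprises at N = 1)
chan3 <- function(a, c) {
  out <- a[, , c, , drop = FALSE]
  dim(out) <- dim(a)[c(1, 2, 4)]
  out
}

# per-pixel channel softmax of (H, W, 2, N) logits
pixel_softmax <- function(logits) {
  m <- pmax(logits[, , 1, , drop = FALSE], logits[, , 2, , drop = FALSE])
  e1 <- exp(logits[, , 1, , drop = FALSE] - m)
  e2 <- exp(logits[, , 2, , drop = FALSE] - m)
  s <- e1 + e2
  out <- logits
  out[, , 1, ] <- e1 / s
  out[, , 2, ] <- e2 / s
  out
}

#' Pixel-wise cross-entropy between a probability map and a binary mask
#'
#' Mean over pixels of `-log p(true channel)`, in nats, with probabilities
#' clamped to `[1e-7, 1 - 1e-7]` for numerical safety.
#'
#' @param pred Per-pixel probability array `(H, W, 2)` or `(H, W, 2, N)`;
#'   channel 2 is the mask (foreground) probability.
#' @param truth Binary mask `(H, W)` or array `(H, W, N)`.
#' @return Scalar loss in nats (non-negative).
#' @export
pixelwise_cross_entropy <- function(pred, truth) {
  if (length(dim(pred)) == 3) dim(pred) <- c(dim(pred), 1L)
  if (is.matrix(truth)) dim(truth) <- c(dim(truth), 1L)
  if (any(pred < 0 | pred > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  dp <- dim(pred)
  if (!all(dp[c(1, 2, 4)] == dim(truth))) stop("pred and truth shapes disagree", call. = FALSE)
  fg <- chan3(pred, 2L)
  bg <- chan3(pred, 1L)
  p_true <- fg * truth + bg * (1 - truth)
  -mean(log(clamp_prob(p_true)))
}

#' Segmentation training schedule
#'
#' Defaults follow the segmentation recipe used throughout: Adam over 50
#' epochs, initial learning rate 1e-4 with a per-epoch multiplicative decay
#' of 0.93 (so the rate at epoch e is `lr0 * decay^e`).
#'
#' @param epochs,lr0,decay,batch_size,seed Schedule fields; `0 < decay <= 1`.
#' @return A `seg_schedule` list.
#' @export
seg_schedule <- function(epochs = 50L, lr0 = 1e-4, decay = 0.93, batch_size = 8L, seed = 1L) {
  if (decay <= 0 || decay > 1) stop("decay must lie in (0, 1]", call. = FALSE)
  structure(list(epochs = as.integer(epochs), lr0 = lr0, decay = decay,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "seg_schedule")
}

#' Train a U-Net on image/mask pairs
#'
#' Adam optimisation of [pixelwise_cross_entropy()] with the schedule's
#' per-epoch learning-rate decay. Seeded and reproducible on one thread.
#'
#' @param model A [build_unet()] model (updated in place).
#' @param data Tibble with list-columns holding images and masks.
#' @param schedule A [seg_schedule()].
#' @param image_col,mask_col Names of the list-columns to use.
#' @return A `unet_fit` with the model and a per-epoch `history` tibble.
#' @export
train_unet <- function(model, data, schedule = seg_schedule(),
                       image_col = "image", mask_col = "fov_mask") {
  stopifnot(inherits(model, "unet_model"))
  images <- data[[image_col]]
  masks <- data[[mask_col]]
  keep <- !vapply(masks, is.null, logical(1))
  images <- images[keep]; masks <- masks[keep]
  n <- length(images)
  if (n == 0) stop("empty training set", call. = FALSE)
  set.seed(schedule$seed)
  layers <- unet_layers(model)
  hw <- dim(images[[1]])
  step <- 0L
  hist <- vector("list", schedule$epochs)
  for (ep in seq_len(schedule$epochs)) {
    lr <- schedule$lr0 * schedule$decay^(ep - 1L)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = schedule$batch_size)) {
      idx <- ord[b0:min(b0 + schedule$batch_size - 1L, n)]
      x <- stack_images(images[idx])
      truth <- array(unlist(masks[idx]), c(hw[1], hw[2], length(idx)))
      logits <- unet_forward(model, x, training = TRUE)
      p <- pixel_softmax(logits)
      fg <- chan3(p, 2L)
      bg <- chan3(p, 1L)
      pt <- fg * truth + bg * (1 - truth)
      loss <- -mean(log(clamp_prob(pt)))
      scale <- 1 / length(pt)
      dlog <- p
      dlog[, , 1, ] <- (bg - (1 - truth)) * scale
      dlog[, , 2, ] <- (fg - truth) * scale
      unet_backward(model, dlog)
      step <- step + 1L
      adam_step(layers, lr, step)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / nb, lr = lr)
  }
  structure(list(model = model, history = dplyr::bind_rows(hist), schedule = schedule),
            class = "unet_fit")
}

#' Predict a binary mask for one image
#'
#' Per-pixel argmax of the softmax map; ties break toward background, so a
#' pixel needs foreground probability strictly above 0.5 to enter the mask.
#'
#' @param model A trained `unet_model` (or `unet_fit`).
#' @param image Matrix matching the model's input size.
#' @return A 0/1 matrix of the same shape.
#' @export
predict_mask <- function(model, image) {
  if (inherits(model, "unet_fit")) model <- model$model
  x <- stack_images(list(image))
  p <- pixel_softmax(unet_forward(model, x, training = FALSE))
  (p[, , 2, 1] > 0.5) * 1
}

#' @rdname predict_mask
#' @param images List of matrices; predicted in minibatches of 32.
#' @return `predict_masks()` returns a list of 0/1 matrices.
#' @export
predict_masks <- function(model, images) {
  if (inherits(model, "unet_fit")) model <- model$model
  out <- vector("list", length(images))
  for (b0 in seq(1L, length(images), by = 32L)) {
    idx <- b0:min(b0 + 31L, length(images))
    x <- stack_images(images[idx])
    p <- pixel_softmax(unet_forward(model, x, training = FALSE))
    for (j in seq_along(idx)) out[[idx[j]]] <- (p[, , 2, j] > 0.5) * 1
  }
  out
}

#' Intersection over union of two binary masks
#'
#' @param a,b 0/1 matrices of identical shape. Two empty masks have IoU 1.
#' @return Scalar in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  inter <- sum(a > 0 & b > 0)
  uni <- sum(a > 0 | b > 0)
  if (uni == 0) return(1)
  inter / uni
}
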