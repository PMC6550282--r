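# Semi-supervised GAN: two-headed discriminator (K-class softmax head plus
# real/fake sigmoid head over a shared trunk), a transposed-convolution
# generator, the four-term loss system, feature-matching generator training,
# and the label-efficiency experiment harness.
#
# The discriminator realises p(y = K+1 | x) — the "this is generated" class —
# as 1 - s, where s is the sigmoid head's real score. With that reading the
# three discriminator terms reduce to
#   L_supervised   = -E log p(y | x, y < K+1)   (softmax head, labeled x)
#   L_unsupervised = -E log s                   (real unlabeled x)
#   L_generated    = -E log (1 - s)             (x ~ G)
# and their sum is the single quantity one backpropagation step minimises.
# The generator is trained on feature matching: the squared distance between
# the batch-mean penultimate discriminator features of fake and real batches.

#' Semi-supervised GAN configuration
#'
#' @param image_size Square input size in pixels (canonical choice 110).
#'   Must be reachable from a 1x1 noise seed map by `gen_layers` stride-2
#'   upsamplings, i.e. `2^gen_layers >= image_size`; any overshoot is
#'   removed by a centred crop after the final upsample.
#' @param n_classes Number of real classes K (>= 2).
#' @param noise_dim Dimension of the generator's Gaussian noise input.
#' @param disc_blocks Discriminator blocks; each block is three convolutions
#'   (two stride-1 and one downstride-2), batch norm after every convolution,
#'   dropout after every downstride convolution, leaky-ReLU activations.
#' @param base_filters Filters in the first discriminator block (doubling per
#'   block, capped at 64).
#' @param feat_dim Width of the penultimate feature layer used for feature
#'   matching.
#' @param gen_layers Stride-2 transposed-convolution layers in the generator
#'   (7 reaches 128, cropped to 110).
#' @param gen_base_filters Width scale of the generator: the layer feeding
#'   the k-th upsampling from the end has `gen_base_filters * 2^(k-1)`
#'   channels, floored at 8 and capped at 64.
#' @param dropout_rate,leak_slope Regularisation and leaky-ReLU slope.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate for both networks (constant, no decay).
#' @param max_rotation,max_shift Augmentation applied to the labeled batches
#'   (which cycle many times per epoch and would otherwise be memorised);
#'   the same limits as the supervised recipe. Set to 0 to disable.
#' @param seed Integer seed.
#' @return A `gan_config`.
#' @export
gan_config <- function(image_size = 110L, n_classes = 4L, noise_dim = 100L,
                       disc_blocks = 3L, base_filters = 16L, feat_dim = 64L,
                       gen_layers = 7L, gen_base_filters = 8L,
                       dropout_rate = 0.3, leak_slope = 0.2,
                       batch_size = 32L, lr = 3e-4, max_rotation = 10,
                       max_shift = 0.1, seed = 1L) {
  if (2^gen_layers < image_size) {
    stop("image_size is not reachable by gen_layers stride-2 upsamplings",
         call. = FALSE)
  }
  if (n_classes < 2) stop("need at least two classes", call. = FALSE)
  structure(list(image_size = as.integer(image_size), n_classes = as.integer(n_classes),
                 noise_dim = as.integer(noise_dim), disc_blocks = as.integer(disc_blocks),
                 base_filters = as.integer(base_filters), feat_dim = as.integer(feat_dim),
                 gen_layers = as.integer(gen_layers),
                 gen_base_filters = as.integer(gen_base_filters),
                 dropout_rate = dropout_rate,
                 leak_slope = leak_slope, batch_size = as.integer(batch_size),
                 lr = lr, max_rotation = max_rotation, max_shift = max_shift,
                 seed = as.integer(seed)),
            class = "gan_config")
}

#' Build the two-headed discriminator
#'
#' Shared convolutional trunk of `disc_blocks` blocks (3x3 filters, two
#' stride-1 convolutions then one downstride-2 convolution, batch norm after
#' each convolution, dropout after each downstride, leaky ReLUs), a final
#' full-field convolution collapsing the remaining spatial map to the
#' penultimate feature vector (the one convolution that is not 3x3), and two
#' heads on those shared features: a K-class softmax head and a sigmoid
#' real/fake head.
#'
#' @param config A [gan_config()].
#' @param seed Optional seed for weight initialisation.
#' @return A `gan_discriminator`.
#' @export
build_discriminator <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gan_config"))
  if (!is.null(seed)) set.seed(seed)
  trunk <- list()
  in_ch <- 1L
  s <- config$image_size
  for (b in seq_len(config$disc_blocks)) {
    f <- min(config$base_filters * 2^(b - 1L), 64L)
    trunk <- c(trunk, list(
      nn_conv(in_ch, f, 3L), nn_bn(f), nn_act("leaky", config$leak_slope),
      nn_conv(f, f, 3L), nn_bn(f), nn_act("leaky", config$leak_slope),
      nn_conv(f, f, 3L, stride = 2L, pad = 1L), nn_bn(f),
      nn_act("leaky", config$leak_slope), nn_dropout(config$dropout_rate)
    ))
    in_ch <- f
    s <- (s + 1L) %/% 2L  # ceil(s / 2) under same-padding stride 2
  }
  feat <- list(nn_conv(in_ch, config$feat_dim, k = s, pad = 0L),
               nn_act("leaky", config$leak_slope), nn_flatten())
  structure(list(config = config, trunk = trunk, feat = feat,
                 head_class = nn_dense(config$feat_dim, config$n_classes, init = "xavier"),
                 head_real = nn_dense(config$feat_dim, 1L, init = "xavier"),
                 final_spatial = s),
            class = "gan_discriminator")
}

disc_layers <- function(d) c(d$trunk, d$feat, list(d$head_class, d$head_real))

# The discriminator's batch-norm running statistics (used at evaluation)
# should describe real images only, so stat tracking is frozen while
# generated batches pass through.
set_bn_tracking <- function(d, on) {
  for (l in disc_layers(d)) if (l$type == "bn") l$freeze_stats <- !on
  invisible(NULL)
}

# Forward pass; x in [-1, 1], shape (H, W, 1, N). Returns the
# DiscriminatorOutput: class probabilities, real score s and the shared
# penultimate features (identical for both heads by construction).
disc_forward <- function(d, x, training = FALSE) {
  h <- run_layers(d$trunk, x, training)
  feats <- run_layers(d$feat, h, training)
  class_logits <- layer_forward(d$head_class, feats, training)
  real_logit <- layer_forward(d$head_real, feats, training)
  list(class_probs = softmax_cols(class_logits),
       s = as.vector(sigmoid(real_logit)),
       features = feats)
}

# Backward from head-logit gradients (either may be zero), through the
# shared trunk; optionally with an extra gradient arriving directly at the
# feature layer (used by feature matching). Returns gradient w.r.t. input.
disc_backward <- function(d, dclass_logits = NULL, dreal_logit = NULL, dfeat = NULL) {
  acc <- NULL
  if (!is.null(dclass_logits)) acc <- layer_backward(d$head_class, dclass_logits)
  if (!is.null(dreal_logit)) {
    g <- layer_backward(d$head_real, dreal_logit)
    acc <- if (is.null(acc)) g else acc + g
  }
  if (!is.null(dfeat)) acc <- if (is.null(acc)) dfeat else acc + dfeat
  acc <- run_layers_bwd(d$feat, acc)
  run_layers_bwd(d$trunk, acc)
}

#' Build the upsampling generator
#'
#' A 1x1 x `noise_dim` Gaussian seed map passes through `gen_layers`
#' stride-2 transposed convolutions (4x4 kernels, batch norm and ReLU on all
#' intermediate layers), doubling the spatial size at every step; the final
#' layer uses Tanh to emit a single-channel image in (-1, 1). If
#' `2^gen_layers` overshoots `image_size`, the output is cropped centrally.
#'
#' @param config A [gan_config()].
#' @param seed Optional seed for weight initialisation.
#' @return A `gan_generator`.
#' @export
build_generator <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gan_config"))
  if (!is.null(seed)) set.seed(seed)
  nl <- config$gen_layers
  layers <- list()
  in_ch <- config$noise_dim
  base <- if (is.null(config$gen_base_filters)) 8L else config$gen_base_filters
  for (i in seq_len(nl - 1L)) {
    out_ch <- min(64L, max(8L, base * 2^(nl - 1L - i)))
    layers <- c(layers, list(nn_convT(in_ch, out_ch, 4L), nn_bn(out_ch), nn_act("relu")))
    in_ch <- out_ch
  }
  layers <- c(layers, list(nn_convT(in_ch, 1L, 4L), nn_act("tanh")))
  full <- 2L^nl
  off <- (full - config$image_size) %/% 2L
  structure(list(config = config, layers = layers, full_size = full, crop_off = off),
            class = "gan_generator")
}

gen_layers_list <- function(g) g$layers

# noise: (noise_dim x N) matrix -> images (image_size, image_size, 1, N) in (-1, 1)
gen_forward <- function(g, z, training = FALSE) {
  x <- array(z, c(1L, 1L, nrow(z), ncol(z)))
  x <- run_layers(g$layers, x, training)
  if (g$crop_off > 0) {
    idx <- g$crop_off + seq_len(g$config$image_size)
    x <- x[idx, idx, , , drop = FALSE]
  }
  x
}

gen_backward <- function(g, dy) {
  if (g$crop_off > 0) {
    full <- array(0, c(g$full_size, g$full_size, 1L, dim(dy)[4]))
    idx <- g$crop_off + seq_len(g$config$image_size)
    full[idx, idx, , ] <- dy
    dy <- full
  }
  run_layers_bwd(g$layers, dy)
}

#' The four GAN loss terms
#'
#' `supervised_loss()` is the batch-mean cross-entropy of the softmax head at
#' the true labels; `unsupervised_loss()` penalises real unlabeled images the
#' discriminator doubts (`-E log s`); `generated_loss()` penalises generated
#' images the discriminator believes (`-E log(1 - s)`). All are in nats with
#' probabilities clamped at `1e-7`. `discriminator_total_loss()` assembles
#' the three parts and their sum — the quantity a single discriminator
#' update minimises.
#'
#' @param output A discriminator output (list with `class_probs` and `s`).
#' @param labels 0-based class labels for the labeled batch.
#' @return Scalar loss in nats; `discriminator_total_loss()` returns a
#'   `gan_loss_parts` list with `L_supervised`, `L_unsupervised`,
#'   `L_generated`, `L_total`.
#' @export
supervised_loss <- function(output, labels) {
  k <- nrow(output$class_probs)
  if (any(labels >= k | labels < 0)) stop("label out of range", call. = FALSE)
  idx <- cbind(as.integer(labels) + 1L, seq_len(ncol(output$class_probs)))
  -mean(log(clamp_prob(output$class_probs[idx])))
}

#' @rdname supervised_loss
#' @export
unsupervised_loss <- function(output) -mean(log(clamp_prob(output$s)))

#' @rdname supervised_loss
#' @export
generated_loss <- function(output) -mean(log(clamp_prob(1 - output$s)))

#' @rdname supervised_loss
#' @param labeled_output,unlabeled_output,generated_output Discriminator
#'   outputs for the labeled, real-unlabeled and generated batches.
#' @export
discriminator_total_loss <- function(labeled_output, labels, unlabeled_output,
                                     generated_output) {
  parts <- list(
    L_supervised = supervised_loss(labeled_output, labels),
    L_unsupervised = unsupervised_loss(unlabeled_output),
    L_generated = generated_loss(generated_output)
  )
  parts$L_total <- parts$L_supervised + parts$L_unsupervised + parts$L_generated
  structure(parts, class = "gan_loss_parts")
}

#' Feature-matching loss for the generator
#'
#' Mean squared difference between the batch-mean penultimate discriminator
#' feature vectors of a generated batch and a real unlabeled batch.
#'
#' @param fake_features,real_features `(feat_dim x N)` feature matrices.
#' @return Scalar loss.
#' @export
feature_matching_loss <- function(fake_features, real_features) {
  mean((rowMeans(fake_features) - rowMeans(real_features))^2)
}

# grad accumulation across the three discriminator passes
zero_acc <- function(layers) lapply(layers, function(l) NULL)

add_grads <- function(acc, layers) {
  for (i in seq_along(layers)) {
    g <- layers[[i]]$g
    if (length(g) == 0) next
    if (is.null(acc[[i]])) {
      acc[[i]] <- g
    } else {
      for (p in names(g)) acc[[i]][[p]] <- acc[[i]][[p]] + g[[p]]
    }
  }
  acc
}

set_grads <- function(layers, acc) {
  for (i in seq_along(layers)) if (!is.null(acc[[i]])) layers[[i]]$g <- acc[[i]]
  invisible(NULL)
}

#' Train the semi-supervised GAN
#'
#' Each iteration performs three passes through the discriminator — a
#' labeled batch scored by the softmax head, an unlabeled batch and a
#' generated batch scored by the sigmoid head — whose losses are summed into
#' one backpropagation step, followed by one generator step on the
#' feature-matching loss. One epoch is defined by the unlabeled set (the
#' labeled batches cycle, so the discriminator sees many epochs of the
#' labeled images). Adam at a constant learning rate for both networks.
#'
#' @param labeled Tibble with an image list-column and 0-based labels.
#' @param unlabeled Tibble with an image list-column (labels ignored). If
#'   empty, training falls back to supervised-only with a warning.
#' @param config A [gan_config()].
#' @param epochs Number of epochs over the unlabeled set.
#' @param test Optional test tibble; accuracy and macro F1 of the classifier
#'   head are logged per epoch.
#' @param label_col,image_col Column names.
#' @param grid_n Number of generator samples drawn (from a fixed noise
#'   matrix) into the per-epoch sample grid.
#' @return An `ssgan_fit`: discriminator, generator, per-epoch `history`
#'   tibble and a list of per-epoch sample grids (arrays in `[0, 1]`).
#' @export
train_ssgan <- function(labeled, unlabeled, config, epochs = 5L, test = NULL,
                        label_col = "view_label", image_col = "image", grid_n = 16L) {
  stopifnot(inherits(config, "gan_config"))
  if (nrow(labeled) == 0) stop("labeled set must be nonempty", call. = FALSE)
  set.seed(config$seed)
  sz <- config$image_size
  rs <- function(imgs) lapply(imgs, function(m) {
    if (!all(dim(m) == c(sz, sz))) m <- resize_nearest(m, sz, sz)
    m
  })
  prep <- function(imgs) lapply(rs(imgs), to_gan_range)
  x_lab <- rs(labeled[[image_col]])  # kept in [0,1]: augmented per batch
  y_lab <- as.integer(labeled[[label_col]])
  x_unl <- prep(unlabeled[[image_col]])
  n_lab <- length(x_lab); n_unl <- length(x_unl)
  supervised_only <- n_unl == 0
  if (supervised_only) {
    warning("empty unlabeled set: falling back to supervised-only training")
  }
  if (!is.null(test)) {
    x_te <- stack_images(prep(test[[image_col]]))
    y_te <- as.integer(test[[label_col]])
  }

  D <- build_discriminator(config)
  G <- build_generator(config)
  dl <- disc_layers(D); gl <- gen_layers_list(G)
  bs <- config$batch_size
  iters <- if (supervised_only) ceiling(n_lab / bs) else ceiling(n_unl / bs)
  z_grid <- matrix(stats::rnorm(config$noise_dim * grid_n), config$noise_dim, grid_n)

  lab_stream <- sample.int(n_lab)
  lab_pos <- 0L
  next_lab_batch <- function() {
    idx <- integer(bs)
    for (i in seq_len(bs)) {
      lab_pos <<- lab_pos + 1L
      if (lab_pos > n_lab) {
        lab_stream <<- sample.int(n_lab)
        lab_pos <<- 1L
      }
      idx[i] <- lab_stream[lab_pos]
    }
    idx
  }

  t_d <- 0L; t_g <- 0L
  hist <- vector("list", epochs)
  grids <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    unl_ord <- if (supervised_only) integer(0) else sample.int(n_unl)
    ep_parts <- c(sup = 0, unsup = 0, gen = 0, fm = 0)
    for (it in seq_len(iters)) {
      acc <- zero_acc(dl)

      # pass 1: labeled -> supervised cross-entropy on the softmax head
      li <- next_lab_batch()
      imgs <- x_lab[li]
      if (config$max_rotation > 0 || config$max_shift > 0) {
        imgs <- lapply(imgs, augment, max_rotation = config$max_rotation,
                       max_shift = config$max_shift)
      }
      xb <- to_gan_range(stack_images(imgs))
      out <- disc_forward(D, xb, training = TRUE)
      ce <- softmax_ce(out$class_probs, y_lab[li])
      disc_backward(D, dclass_logits = ce$dlogits)
      acc <- add_grads(acc, dl)
      ep_parts["sup"] <- ep_parts["sup"] + ce$loss

      if (!supervised_only) {
        # pass 2: unlabeled -> -E log s on the sigmoid head
        start <- (it - 1L) * bs + 1L
        ui <- unl_ord[start:min(start + bs - 1L, n_unl)]
        xu <- stack_images(x_unl[ui])
        out_u <- disc_forward(D, xu, training = TRUE)
        nu <- length(out_u$s)
        dz <- matrix(-(1 - out_u$s) / nu, 1L, nu)
        disc_backward(D, dreal_logit = dz)
        acc <- add_grads(acc, dl)
        ep_parts["unsup"] <- ep_parts["unsup"] + unsupervised_loss(out_u)

        # pass 3: generated -> -E log(1 - s); BN stats track real data only
        z <- matrix(stats::rnorm(config$noise_dim * bs), config$noise_dim, bs)
        xf <- gen_forward(G, z, training = TRUE)
        set_bn_tracking(D, FALSE)
        out_f <- disc_forward(D, xf, training = TRUE)
        set_bn_tracking(D, TRUE)
        dz <- matrix(out_f$s / bs, 1L, bs)
        disc_backward(D, dreal_logit = dz)
        acc <- add_grads(acc, dl)
        ep_parts["gen"] <- ep_parts["gen"] + generated_loss(out_f)
      }

      set_grads(dl, acc)
      t_d <- t_d + 1L
      adam_step(dl, config$lr, t_d)

      if (!supervised_only) {
        # generator step: feature matching against the iteration's unlabeled
        # batch (its features were computed in pass 2)
        f_real <- out_u$features
        z <- matrix(stats::rnorm(config$noise_dim * bs), config$noise_dim, bs)
        xf <- gen_forward(G, z, training = TRUE)
        set_bn_tracking(D, FALSE)
        out_f <- disc_forward(D, xf, training = TRUE)
        set_bn_tracking(D, TRUE)
        fd <- dim(out_f$features)
        diff <- rowMeans(out_f$features) - rowMeans(f_real)
        ep_parts["fm"] <- ep_parts["fm"] + mean(diff^2)
        dfeat <- matrix(2 * diff / (fd[1] * fd[2]), fd[1], fd[2])
        dx <- disc_backward(D, dfeat = dfeat)
        gen_backward(G, dx)
        t_g <- t_g + 1L
        adam_step(gl, config$lr, t_g)
      }
    }

    row <- tibble::tibble(epoch = ep,
                          L_supervised = ep_parts[["sup"]] / iters,
                          L_unsupervised = ep_parts[["unsup"]] / iters,
                          L_generated = ep_parts[["gen"]] / iters,
                          feature_matching = ep_parts[["fm"]] / iters,
                          test_accuracy = NA_real_, test_f1 = NA_real_)
    if (!is.null(test)) {
      pr <- disc_forward(D, x_te, training = FALSE)$class_probs
      pred <- max.col(t(pr)) - 1L
      row$test_accuracy <- mean(pred == y_te)
      row$test_f1 <- macro_f1(y_te, pred, config$n_classes)
    }
    hist[[ep]] <- row
    grids[[ep]] <- pmin(pmax(from_gan_range(gen_forward(G, z_grid)), 0), 1)
  }

  structure(list(discriminator = D, generator = G, config = config,
                 history = dplyr::bind_rows(hist), sample_grids = grids,
                 iters_per_epoch = iters),
            class = "ssgan_fit")
}

#' Class probabilities from the discriminator's softmax head
#'
#' @param object An `ssgan_fit` or `gan_discriminator`.
#' @param images List of `[0, 1]` matrices (resized internally).
#' @param ... Unused.
#' @return An `N x K` probability matrix.
#' @export
predict.ssgan_fit <- function(object, images, ...) {
  d <- object$discriminator
  sz <- object$config$image_size
  x <- stack_images(lapply(images, function(m) {
    if (!all(dim(m) == c(sz, sz))) m <- resize_nearest(m, sz, sz)
    to_gan_range(m)
  }))
  t(disc_forward(d, x, training = FALSE)$class_probs)
}

# Select exactly n labeled frames per class, taking whole studies first so
# the labeled subset respects study grouping.
select_labels_per_class <- function(data, n_per_class, label_col = "view_label") {
  picked <- logical(nrow(data))
  for (cl in sort(unique(data[[label_col]]))) {
    rows <- which(data[[label_col]] == cl)
    studies <- sample(unique(data$study_id[rows]))
    got <- integer(0)
    for (s in studies) {
      cand <- rows[data$study_id[rows] == s]
      got <- c(got, cand)
      if (length(got) >= n_per_class) break
    }
    picked[got[seq_len(min(n_per_class, length(got)))]] <- TRUE
  }
  picked
}

#' Label-efficiency curve for the semi-supervised GAN
#'
#' For each level `n` the harness keeps exactly `n` labels per class (taking
#' whole studies first, so labeling respects study grouping), treats the
#' remaining pool as unlabeled, trains the GAN, and evaluates the classifier
#' head on a fixed held-out test set.
#'
#' @param data Labeled pool tibble (image list-column, labels, `study_id`).
#' @param levels Integer vector of labels-per-class levels.
#' @param unlabeled Extra unlabeled tibble appended to the leftover pool.
#' @param config A [gan_config()].
#' @param test Held-out test tibble.
#' @param epochs Training epochs per run.
#' @param seeds Integer vector; each level is run once per seed.
#' @param label_col Label column name.
#' @return A `label_efficiency` tibble: `labels_per_class`, `seed`,
#'   `test_accuracy`.
#' @export
label_efficiency_curve <- function(data, levels, unlabeled = NULL, config, test,
                                   epochs = 2L, seeds = 1L, label_col = "view_label") {
  rows <- list()
  for (n_per in levels) {
    for (sd in seeds) {
      set.seed(sd)
      keep <- select_labels_per_class(data, n_per, label_col)
      lab <- data[keep, ]
      unl <- data[!keep, ]
      if (!is.null(unlabeled)) unl <- dplyr::bind_rows(unl, unlabeled)
      cfg <- config
      cfg$seed <- as.integer(sd)
      fit <- train_ssgan(lab, unl, cfg, epochs = epochs, test = test,
                         label_col = label_col)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        labels_per_class = n_per, seed = sd,
        test_accuracy = fit$history$test_accuracy[nrow(fit$history)]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("label_efficiency", class(out))
  out
}
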