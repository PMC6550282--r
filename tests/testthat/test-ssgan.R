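fake_output <- function(probs, s) {
  list(class_probs = if (is.matrix(probs)) probs else matrix(probs, ncol = 1),
       s = s, features = NULL)
}

test_that("the three loss terms match hand-computed values in nats", {
  out <- fake_output(c(0.7, 0.2, 0.1), s = 0.5)
  expect_equal(supervised_loss(out, 0L), -log(0.7), tolerance = 1e-6)
  expect_equal(supervised_loss(fake_output(rep(1 / 15, 15), 0.5), 7L), log(15),
               tolerance = 1e-6)
  one_hot <- fake_output(c(1, 0, 0), 0.5)
  expect_lt(supervised_loss(one_hot, 0L), 1e-6)
  expect_error(supervised_loss(out, 3L), "out of range")

  expect_equal(unsupervised_loss(fake_output(1, s = 1)), 0, tolerance = 1e-6)
  expect_equal(unsupervised_loss(fake_output(1, s = 0.5)), log(2), tolerance = 1e-6)
  expect_equal(unsupervised_loss(fake_output(1, s = 0.8)), -log(0.8), tolerance = 1e-6)

  expect_equal(generated_loss(fake_output(1, s = 0)), 0, tolerance = 1e-6)
  expect_equal(generated_loss(fake_output(1, s = 0.5)), log(2), tolerance = 1e-6)
  expect_equal(generated_loss(fake_output(1, s = 0.9)), -log(0.1), tolerance = 1e-5)
})

test_that("the total discriminator loss is the exact sum of its parts", {
  parts <- discriminator_total_loss(fake_output(c(0.7, 0.2, 0.1), 1), 0L,
                                    fake_output(c(1, 0, 0), 0.8),
                                    fake_output(c(1, 0, 0), 0.9))
  expect_equal(parts$L_supervised, -log(0.7), tolerance = 1e-6)
  expect_equal(parts$L_unsupervised, -log(0.8), tolerance = 1e-6)
  expect_equal(parts$L_generated, -log(0.1), tolerance = 1e-5)
  expect_identical(parts$L_total,
                   parts$L_supervised + parts$L_unsupervised + parts$L_generated)
  expect_equal(parts$L_total, 2.8824, tolerance = 1e-4)
})

test_that("a perfect frozen discriminator drives the total loss to zero", {
  k <- 4
  lab <- fake_output(diag(k)[, sample(k, 10, replace = TRUE)], s = rep(1, 10))
  labels <- max.col(t(lab$class_probs)) - 1L
  parts <- discriminator_total_loss(lab, labels,
                                    fake_output(matrix(1 / k, k, 10), rep(1, 10)),
                                    fake_output(matrix(1 / k, k, 10), rep(0, 10)))
  expect_lt(parts$L_total, 1e-5)
})

test_that("feature matching compares batch-mean features and ignores sample order", {
  f <- matrix(rnorm(8 * 5), 8, 5)
  expect_equal(feature_matching_loss(f, f), 0)
  expect_equal(feature_matching_loss(matrix(0, 2, 3), matrix(1, 2, 3)), 1)
  perm <- f[, sample(5)]
  g <- matrix(rnorm(8 * 5), 8, 5)
  expect_equal(feature_matching_loss(f, g), feature_matching_loss(perm, g),
               tolerance = 1e-12)
})

test_that("batch losses equal independent per-sample scalar-loop oracles", {
  set.seed(20)
  for (r in 1:10) {
    k <- sample(2:6, 1); n <- sample(3:8, 1)
    raw <- matrix(runif(k * n), k, n)
    probs <- sweep(raw, 2, colSums(raw), "/")
    labels <- sample(0:(k - 1), n, replace = TRUE)
    s <- runif(n)
    acc_sup <- 0; acc_uns <- 0; acc_gen <- 0
    for (i in 1:n) {
      acc_sup <- acc_sup - log(probs[labels[i] + 1, i])
      acc_uns <- acc_uns - log(s[i])
      acc_gen <- acc_gen - log(1 - s[i])
    }
    out <- fake_output(probs, s)
    expect_equal(supervised_loss(out, labels), acc_sup / n, tolerance = 1e-9)
    expect_equal(unsupervised_loss(out), acc_uns / n, tolerance = 1e-9)
    expect_equal(generated_loss(out), acc_gen / n, tolerance = 1e-9)
  }
})

test_that("discriminator downsamples 110 by ceil-halving and emits a simplex", {
  cfg <- gan_config(image_size = 110L, n_classes = 5L, disc_blocks = 3L,
                    base_filters = 8L, feat_dim = 16L, gen_layers = 7L, seed = 1)
  d <- build_discriminator(cfg, seed = 1)
  expect_equal(d$final_spatial, 14L)  # 110 -> 55 -> 28 -> 14
  x <- array(runif(110 * 110 * 3) * 2 - 1, c(110, 110, 1, 3))
  out <- echodl:::disc_forward(d, x)
  expect_equal(colSums(out$class_probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(out$s > 0 & out$s < 1))
  # both heads read the same shared features
  cl <- echodl:::layer_forward(d$head_class, out$features)
  rl <- echodl:::layer_forward(d$head_real, out$features)
  expect_equal(echodl:::softmax_cols(cl), out$class_probs)
  expect_equal(as.vector(echodl:::sigmoid(rl)), out$s)
})

test_that("generator upsamples to 2^layers, crops centrally, and stays in (-1,1)", {
  cfg <- gan_config(image_size = 110L, n_classes = 4L, gen_layers = 7L,
                    noise_dim = 16L, seed = 2)
  g <- build_generator(cfg, seed = 2)
  expect_equal(g$full_size, 128L)
  expect_equal(g$crop_off, 9L)
  z <- matrix(rnorm(16 * 2), 16, 2)
  y <- echodl:::gen_forward(g, z)
  expect_equal(dim(y), c(110L, 110L, 1L, 2L))
  expect_true(all(y > -1 & y < 1))
  expect_identical(echodl:::gen_forward(g, z), y)  # same noise, same images
  expect_error(gan_config(image_size = 300L, gen_layers = 7L), "not reachable")
})

test_that("an epoch is defined by the unlabeled set and training logs metrics", {
  spec <- spec_3232()
  lab <- generate_phantom_dataset(spec, n_studies = 8, seed = 31)
  unl <- generate_phantom_dataset(spec, n_studies = 10, seed = 32)  # 20 frames
  cfg <- gan_config(image_size = 32L, n_classes = 4L, disc_blocks = 1L,
                    base_filters = 4L, feat_dim = 8L, gen_layers = 5L,
                    noise_dim = 8L, batch_size = 8L, seed = 33)
  fit <- train_ssgan(lab, unl, cfg, epochs = 1L, test = lab)
  expect_equal(fit$iters_per_epoch, ceiling(20 / 8))
  expect_true(all(is.finite(fit$history$L_supervised)))
  grid <- fit$sample_grids[[1]]
  expect_true(all(grid >= 0 & grid <= 1))
  probs <- predict(fit, lab$image)
  expect_equal(rowSums(probs), rep(1, nrow(lab)), tolerance = 1e-6)
  expect_warning(train_ssgan(lab, unl[0, ], cfg, epochs = 1L), "supervised-only")
})

test_that("label subsets are study-respecting, exact and seeded", {
  b <- data.frame(study_id = rep(sprintf("s%02d", 1:20), each = 2),
                  view_label = rep(rep(0:3, 5), each = 2))
  b <- tibble::as_tibble(b)
  set.seed(40)
  k1 <- echodl:::select_labels_per_class(b, 3L)
  expect_equal(unname(tapply(k1, b$view_label, sum)), rep(3L, 4), ignore_attr = TRUE)
  set.seed(40)
  expect_identical(echodl:::select_labels_per_class(b, 3L), k1)
  # whole studies enter before being trimmed: selected frames of size-2 studies
  # come in pairs except at most one trim per class
  sel <- b[k1, ]
  per_study <- table(sel$study_id)
  expect_lte(sum(per_study == 1), 4)
})
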