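test_that("configuration invariants are enforced", {
  expect_error(unet_config(60, 80, depth = 3L), "divisible")
  expect_error(unet_config(64, 80, max_filters = 1024L), "below 1024")
})

test_that("encoder filter ladder doubles from the base and is capped", {
  m <- build_unet(unet_config(64L, 80L, base_filters = 16L, depth = 3L,
                              max_filters = 512L), seed = 1)
  expect_equal(m$filters, c(16L, 32L, 64L))
  expect_equal(m$bottleneck_filters, 128L)
  m2 <- build_unet(unet_config(32L, 32L, base_filters = 256L, depth = 2L,
                               max_filters = 512L), seed = 1)
  expect_equal(m2$filters, c(256L, 512L))
  expect_equal(m2$bottleneck_filters, 512L)
})

test_that("forward pass emits a finite per-pixel softmax map of the input shape", {
  m <- build_unet(unet_config(32L, 40L, base_filters = 4L, depth = 2L), seed = 5)
  x <- array(runif(32 * 40 * 2), c(32, 40, 1, 2))
  logits <- echodl:::unet_forward(m, x, training = FALSE)
  expect_equal(dim(logits), c(32L, 40L, 2L, 2L))
  expect_true(all(is.finite(logits)))
  p <- echodl:::pixel_softmax(logits)
  expect_lt(max(abs(p[, , 1, ] + p[, , 2, ] - 1)), 1e-6)
})

test_that("pixel-wise cross-entropy matches hand values and a scalar-loop oracle", {
  truth <- matrix(c(1, 0, 0, 1), 2, 2)
  perfect <- array(0, c(2, 2, 2))
  perfect[, , 1] <- 1 - truth
  perfect[, , 2] <- truth
  expect_lt(pixelwise_cross_entropy(perfect, truth), 1e-6)

  uniform <- array(0.5, c(2, 2, 2))
  expect_equal(pixelwise_cross_entropy(uniform, truth), log(2), tolerance = 1e-9)

  single <- array(c(0.75, 0.25), c(1, 1, 2))
  expect_equal(pixelwise_cross_entropy(single, matrix(1, 1, 1)), -log(0.25),
               tolerance = 1e-9)

  expect_error(pixelwise_cross_entropy(array(1.2, c(1, 1, 2)), matrix(1, 1, 1)),
               "\\[0,1\\]")

  # independent per-pixel scalar loop on random maps
  set.seed(6)
  for (r in 1:20) {
    p2 <- array(runif(8 * 8), c(8, 8, 1))
    pred <- array(0, c(8, 8, 2))
    pred[, , 2] <- p2
    pred[, , 1] <- 1 - p2
    tr <- matrix(rbinom(64, 1, 0.5), 8, 8)
    acc <- 0
    for (i in 1:8) for (j in 1:8) {
      pt <- if (tr[i, j] == 1) pred[i, j, 2] else pred[i, j, 1]
      acc <- acc - log(min(max(pt, 1e-7), 1 - 1e-7))
    }
    expect_equal(pixelwise_cross_entropy(pred, tr), acc / 64, tolerance = 1e-9)
  }
})

test_that("mask prediction thresholds at strict argmax with ties to background", {
  m <- build_unet(unet_config(16L, 16L, base_filters = 4L, depth = 2L), seed = 2)
  # force the final conv to emit exact ties
  m$final$W[] <- 0
  m$final$b[] <- c(0, 0)
  img <- matrix(runif(256), 16, 16)
  expect_true(all(predict_mask(m, img) == 0))
  m$final$b[] <- c(-10, 10)  # overwhelming foreground logit
  expect_true(all(predict_mask(m, img) == 1))
})

test_that("training reduces the loss, follows the decay schedule, and is seeded", {
  spec <- phantom_spec(32L, 40L)
  d <- generate_phantom_dataset(spec, n_studies = 10, seed = 21)
  mk <- function() build_unet(unet_config(32L, 40L, base_filters = 4L, depth = 2L,
                                          dropout_rate = 0.2), seed = 3)
  sch <- seg_schedule(epochs = 3L, lr0 = 1e-3, decay = 0.93, batch_size = 4L, seed = 4)
  f1 <- train_unet(mk(), d, sch)
  expect_lt(f1$history$loss[3], f1$history$loss[1])
  expect_equal(f1$history$lr, 1e-3 * 0.93^(0:2))
  f2 <- train_unet(mk(), d, sch)
  expect_identical(f1$history, f2$history)
  expect_error(train_unet(mk(), d[0, ], sch), "empty")
})

test_that("IoU is 1 on identical masks, 0 on disjoint ones, 1 when both empty", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, 1 - a), 0)
  expect_equal(mask_iou(a * 0, a * 0), 1)
  expect_equal(mask_iou(a, matrix(1, 2, 2)), 0.5)
})
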