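test_that("resolution design rules match the printed recipe", {
  expect_equal(default_config_for_resolution(30, 40, 4)$pooling, "average")
  expect_equal(default_config_for_resolution(60, 80, 4)$pooling, "max")
  expect_equal(default_config_for_resolution(120, 160, 4)$pooling, "max")
  expect_equal(default_config_for_resolution(120, 160, 4, masked_input = TRUE)$pooling,
               "average")
  big <- default_config_for_resolution(240, 320, 15)
  expect_equal(big$conv_blocks[[1]]$filter_size, 7L)
  expect_equal(big$conv_blocks[[2]]$filter_size, 7L)
  expect_true(all(vapply(big$conv_blocks[-(1:2)], `[[`, integer(1),
                         "filter_size") == 3L))
  expect_error(cnn_config(32, 32, list(list(n_convs = 1L, filters = 8L,
                                            filter_size = 4L))), "odd")
})

test_that("learning rate decays multiplicatively per epoch", {
  sch <- train_schedule(lr0 = 0.02, decay = 0.85)
  expect_equal(lr_at_epoch(sch, 0), 0.02)
  expect_equal(lr_at_epoch(sch, 1), 0.017)
  expect_equal(lr_at_epoch(train_schedule(lr0 = 0.02, decay = 1), 9), 0.02)
})

test_that("early stopping fires after patience non-improving epochs, keeping the best", {
  es <- echodl:::early_stop_epoch(c(1.0, 1.1, 1.2), patience = 2L)
  expect_equal(es$stop_after, 3L)
  expect_equal(es$best, 1L)
  es2 <- echodl:::early_stop_epoch(c(1.0, 0.9, 0.8), patience = 2L)
  expect_true(is.na(es2$stop_after))
  expect_equal(es2$best, 3L)
  # recovery resets the streak; two later flat epochs still trigger the stop
  es3 <- echodl:::early_stop_epoch(c(1.0, 1.1, 0.8, 0.9, 0.95), patience = 2L)
  expect_equal(es3$stop_after, 5L)
  expect_equal(es3$best, 3L)
  es4 <- echodl:::early_stop_epoch(c(1.0, 1.1, 0.8, 0.9), patience = 2L)
  expect_true(is.na(es4$stop_after))
})

test_that("softmax probabilities are a simplex and ensembles average them", {
  cfg <- default_config_for_resolution(16, 20, 3)
  m1 <- build_cnn(cfg, seed = 1)
  m2 <- build_cnn(cfg, seed = 2)
  set.seed(3)
  imgs <- lapply(1:5, function(i) matrix(runif(16 * 20), 16, 20))
  p1 <- predict(m1, imgs)
  p2 <- predict(m2, imgs)
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-6)
  pe <- ensemble_predict(list(m1, m2), imgs)
  expect_equal(pe, (p1 + p2) / 2, tolerance = 1e-12)
  expect_equal(rowSums(pe), rep(1, 5), tolerance = 1e-6)
  expect_equal(ensemble_predict(list(m1), imgs), p1)
})

small_cnn_data <- function(n_per_class = 10, seed = 30) {
  spec <- phantom_spec(32L, 40L)
  d <- generate_phantom_dataset(spec, n_studies = n_per_class * 4, seed = seed)
  d <- split_by_study(d, c(train = 0.7, val = 0.3, test = 0), seed = seed)
  d
}

test_that("training a small classifier beats chance, restores the best epoch, and is seeded", {
  d <- small_cnn_data()
  mk <- function() build_cnn(default_config_for_resolution(32, 40, 4), seed = 9)
  sch <- train_schedule(max_epochs = 3L, batch_size = 16L, seed = 10)
  f1 <- train_cnn(mk(), d, sch)
  expect_gt(f1$history$train_acc[nrow(f1$history)], 0.25)
  # restored weights reproduce the best recorded validation loss
  va <- d[d$split == "val", ]
  probs <- predict(f1$model, va$image)
  vl <- echodl:::softmax_ce(t(probs), va$view_label)$loss
  expect_equal(vl, min(f1$history$val_loss), tolerance = 1e-8)
  f2 <- train_cnn(mk(), d, sch)
  drop_t <- function(h) h[setdiff(names(h), "seconds")]
  expect_identical(drop_t(f1$history), drop_t(f2$history))
  expect_error(train_cnn(mk(), d[d$split == "val", ], sch), "empty training split")
})

test_that("two-stage transfer freezes are exact and stages train the right parts", {
  d <- small_cnn_data()
  src <- build_cnn(default_config_for_resolution(32, 40, 4), seed = 11)
  train_cnn(src, d, train_schedule(max_epochs = 1L, batch_size = 16L, seed = 12))
  d2 <- d
  d2$lvh_label <- as.integer(d2$view_label == 3L)
  tf <- two_stage_transfer(src, d2,
                           stage1 = train_schedule(lr0 = 0.025, decay = 0.85,
                                                   max_epochs = 1L, seed = 13),
                           stage2 = train_schedule(lr0 = 0.001, decay = 0.9,
                                                   max_epochs = 1L, seed = 14),
                           seed = 15)
  # stage-1 froze the trunk: bit-identical to the source parameters
  for (i in seq_along(src$trunk)) {
    for (p in src$trunk[[i]]$params) {
      expect_identical(tf$trunk_after_stage1[[i]][[p]], src$trunk[[i]][[p]])
    }
  }
  # stage-2 froze the head: parameters bit-identical to the end of stage 1
  for (i in seq_along(tf$model$head)) {
    for (p in tf$model$head[[i]]$params) {
      expect_identical(tf$model$head[[i]][[p]], tf$head_after_stage1[[i]][[p]])
    }
  }
  expect_equal(nrow(tf$stage1), 1L)
  expect_equal(tf$stage1$lr, 0.025)
  expect_equal(tf$stage2$lr, 0.001)
})

test_that("the resolution study returns one row per resolution with timings", {
  d <- small_cnn_data(n_per_class = 5)
  out <- resolution_study(list(c(16L, 20L), c(32L, 40L)), d,
                          train_schedule(max_epochs = 2L, batch_size = 16L, seed = 16))
  expect_equal(nrow(out), 2L)
  expect_equal(out$resolution, c("16x20", "32x40"))
  expect_true(all(out$seconds_per_epoch > 0))
  expect_true(all(out$val_accuracy >= 0 & out$val_accuracy <= 1))
})
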