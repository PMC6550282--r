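# Shared fixtures: phantom specs, datasets and trained models are generated
# in code and memoised so expensive fits are paid for once per test run.

the_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = the_cache)) assign(key, fn(), envir = the_cache)
  get(key, envir = the_cache)
}

spec_6480 <- function(seed = NULL) phantom_spec(height = 64L, width = 80L, seed = seed)

spec_3232 <- function(seed = NULL) phantom_spec(height = 32L, width = 32L, seed = seed)


# standard supervised bank: 500 studies x 2 frames at 64x80, study split
bank_6480 <- function() memo("bank_6480", function() {
  d <- generate_phantom_dataset(spec_6480(), n_studies = 500, seed = 42)
  split_by_study(d, c(train = 0.7, val = 0.1, test = 0.2), seed = 7)
})

# 200 LV-view samples (balanced LVH) with ground-truth LV masks, plus 50 held out
lv_set <- function(n, seed) {
  spec <- spec_6480()
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    sm <- render_phantom(spec, spec$lv_class_index, lvh = (i - 1L) %% 2L)
    tibble::tibble(sample_id = sprintf("LV%04d", i), path = NA_character_,
                   study_id = sprintf("LVS%04d", i),
                   view_label = sm$view_label, lvh_label = sm$lvh_label,
                   split = NA_character_, image = list(sm$image),
                   fov_mask = list(sm$fov_mask), lv_mask = list(sm$lv_mask))
  })
  dplyr::bind_rows(rows)
}

# field-of-view U-Net: 200 training phantoms at 64x80, short high-rate schedule
get_fov_unet <- function() memo("fov_unet", function() {
  train <- generate_phantom_dataset(spec_6480(), n_studies = 100, seed = 100)
  m <- build_unet(unet_config(64L, 80L, base_filters = 8L, depth = 3L,
                              dropout_rate = 0.25), seed = 1)
  train_unet(m, train, seg_schedule(epochs = 6L, lr0 = 3e-4, decay = 0.93,
                                    batch_size = 8L, seed = 1))
  m
})

# the LV is a small, speckled target, so its U-Net gets the full 10 epochs
get_lv_unet <- function() memo("lv_unet", function() {
  train <- lv_set(200, seed = 300)
  m <- build_unet(unet_config(64L, 80L, base_filters = 8L, depth = 3L,
                              dropout_rate = 0.25), seed = 2)
  train_unet(m, train, seg_schedule(epochs = 10L, lr0 = 3e-4, decay = 0.93,
                                    batch_size = 8L, seed = 2),
             mask_col = "lv_mask")
  m
})

# view CNN on raw images (metadata band present)
get_cnn_unmasked <- function() memo("cnn_unmasked", function() {
  d <- bank_6480()
  cfg <- default_config_for_resolution(64L, 80L, 4L)
  m <- build_cnn(cfg, seed = 1)
  train_cnn(m, d, train_schedule(max_epochs = 10L, seed = 1))
  m
})

# the same bank masked with the FoV U-Net's predicted masks
masked_bank <- function() memo("masked_bank", function() {
  d <- bank_6480()
  unet <- get_fov_unet()
  d$image <- Map(apply_mask, d$image, predict_masks(unet, d$image))
  d
})

get_cnn_masked <- function() memo("cnn_masked", function() {
  d <- masked_bank()
  cfg <- default_config_for_resolution(64L, 80L, 4L, masked_input = TRUE)
  m <- build_cnn(cfg, seed = 1)
  train_cnn(m, d, train_schedule(max_epochs = 9L, seed = 1))
  m
})

accuracy_on <- function(model, data) {
  probs <- predict(model, data$image)
  mean(max.col(probs) - 1L == data$view_label)
}

# LVH set masked by the LV U-Net's predictions, study-split
lvh_bank <- function() memo("lvh_bank", function() {
  d <- lv_set(240, seed = 500)
  unet <- get_lv_unet()
  d$image <- Map(apply_mask, d$image, predict_masks(unet, d$image))
  split_by_study(d, c(train = 0.6, val = 0.15, test = 0.25), seed = 11)
})

# Semi-supervised bank: phantoms rendered at the standard 64x80 benchmark
# resolution and downsampled to a 28x28 square for the GAN, mirroring the
# acquisition-then-downsample protocol (full frames squashed to a small
# square before adversarial training).
gan_bank <- function() memo("gan_bank", function() {
  rs <- function(d) {
    d$image <- lapply(d$image, resize_nearest, 28L, 28L)
    d
  }
  pool <- generate_phantom_dataset(spec_6480(), n_studies = 1020, seed = 42)
  test <- generate_phantom_dataset(spec_6480(), n_studies = 100, seed = 4242)
  list(pool = rs(pool), test = rs(test))
})

gan_cfg_28 <- function(seed = 1L) {
  gan_config(image_size = 28L, n_classes = 4L, disc_blocks = 2L,
             base_filters = 8L, feat_dim = 64L, gen_layers = 5L,
             gen_base_filters = 4L, dropout_rate = 0.3, batch_size = 32L,
             seed = seed)
}

# one SSGAN run vs one supervised run at 10 labels/class (shared by the
# data-efficiency and determinism checks)
ssgan_vs_supervised <- function(seed, epochs = 5L) {
  b <- gan_bank()
  set.seed(seed)
  keep <- echodl:::select_labels_per_class(b$pool, 10L)
  lab <- b$pool[keep, ]
  unl <- b$pool[!keep, ][seq_len(2000), ]
  fit <- train_ssgan(lab, unl, gan_cfg_28(seed), epochs = epochs, test = b$test)
  gan_acc <- fit$history$test_accuracy[epochs]

  lab2 <- lab
  lab2$split <- "train"
  m <- build_cnn(default_config_for_resolution(28L, 28L, 4L), seed = seed)
  train_cnn(m, lab2, train_schedule(max_epochs = 20L, batch_size = 16L, seed = seed))
  sup_acc <- accuracy_on(m, b$test)
  list(gan = gan_acc, supervised = sup_acc, fit = fit)
}

get_ssgan_runs <- function() memo("ssgan_runs", function() {
  lapply(1:3, ssgan_vs_supervised)
})

# Ring fraction of the bright myocardium inside the LV mask, measured on
# zero-speckle renders where ring (0.85*gain) and cavity (0.06*gain) pixels
# separate cleanly at 0.3. The fraction is 1 - (1 - w)^2 of the LV area, so
# it is monotone in the wall-thickness fraction w by construction.
ring_fraction <- function(spec, lvh, seed) {
  stopifnot(spec$speckle_strength == 0)
  sm <- render_phantom(spec, spec$lv_class_index, lvh = lvh, seed = seed)
  ring <- sum(sm$lv_mask == 1 & sm$image > 0.3)
  ring / max(1, sum(sm$lv_mask))
}
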