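test_that("rendering is bit-identical under a repeated seed", {
  spec <- spec_6480()
  a <- render_phantom(spec, 1L, seed = 7)
  b <- render_phantom(spec, 1L, seed = 7)
  expect_identical(a, b)
  d1 <- generate_phantom_dataset(spec, n_studies = 6, seed = 5)
  d2 <- generate_phantom_dataset(spec, n_studies = 6, seed = 5)
  expect_identical(d1, d2)
})

test_that("without speckle and metadata band, everything outside the sector is 0", {
  spec <- phantom_spec(64L, 80L, speckle_strength = 0, metadata_band = FALSE)
  sm <- render_phantom(spec, 0L, seed = 1)
  expect_true(all(sm$image[sm$fov_mask == 0] == 0))
})

test_that("myocardial ring is thicker for LVH and a threshold separates the classes", {
  # measured at a fine grid so ellipse pixelation cannot blur the separation
  spec <- phantom_spec(160L, 200L, speckle_strength = 0, metadata_band = FALSE)
  normal <- vapply(1:50, function(s) ring_fraction(spec, 0L, s), numeric(1))
  lvh <- vapply(51:100, function(s) ring_fraction(spec, 1L, s), numeric(1))
  expect_gt(mean(lvh), mean(normal))
  # separability floor: one threshold classifies all 100 draws correctly
  expect_gt(min(lvh), max(normal))
  thr <- (max(normal) + min(lvh)) / 2
  expect_equal(mean(c(normal < thr, lvh > thr)), 1)
})

test_that("dataset layout: counts, study grouping and exact LVH quota", {
  spec <- spec_6480()
  d <- generate_phantom_dataset(spec, n_studies = 10, frames_per_study = 2, seed = 1)
  expect_equal(nrow(d), 20L)
  expect_equal(length(unique(d$study_id)), 10L)
  # frames of a study share view and LVH status
  per_study <- dplyr::summarise(dplyr::group_by(d, study_id),
                                nv = dplyr::n_distinct(view_label),
                                nl = dplyr::n_distinct(lvh_label))
  expect_true(all(per_study$nv == 1))
  expect_true(all(per_study$nl == 1))

  d0 <- generate_phantom_dataset(spec, n_studies = 40, lvh_fraction = 0, seed = 2)
  expect_false(any(d0$lvh_label == 1, na.rm = TRUE))

  # quota allocation is exact: 100 LV-view studies at 0.2 give exactly 20
  spec2 <- phantom_spec(48L, 64L, n_view_classes = 2L, lv_class_index = 1L)
  dq <- generate_phantom_dataset(spec2, n_studies = 200, frames_per_study = 1,
                                 lvh_fraction = 0.2, seed = 3)
  expect_equal(sum(dq$lvh_label == 1, na.rm = TRUE), 20L)
})

test_that("sample invariants hold over many generated phantoms", {
  spec <- phantom_spec(48L, 64L)
  band <- ceiling(0.08 * 48)
  set.seed(99)
  for (i in 1:500) {
    vc <- (i - 1L) %% 4L
    lvh <- if (vc == spec$lv_class_index) i %% 2L else NULL
    sm <- render_phantom(spec, vc, lvh = lvh)
    expect_true(all(sm$image >= 0 & sm$image <= 1))
    # anatomy stays inside the field of view except the metadata band
    body <- sm$image[(band + 1):48, ]
    expect_true(all(body[sm$fov_mask[(band + 1):48, ] == 0] == 0))
    if (vc == spec$lv_class_index) {
      expect_false(is.na(sm$lvh_label))
      expect_true(all(sm$lv_mask <= sm$fov_mask))
    } else {
      expect_null(sm$lv_mask)
      expect_true(is.na(sm$lvh_label))
    }
  }
})

test_that("invalid render requests raise domain errors", {
  spec <- spec_6480()
  expect_error(render_phantom(spec, 4L, lvh = 1L), "0..K-1")
  expect_error(render_phantom(spec, spec$lv_class_index), "lvh must be supplied")
  expect_error(render_phantom(spec, 0L, lvh = 1L), "without an LV")
  expect_error(phantom_spec(n_view_classes = 16L), "chamber layouts")
  expect_error(phantom_spec(wall_thickness_normal = c(0.1, 0.4),
                            wall_thickness_lvh = c(0.3, 0.5)), "separable")
})

test_that("PNG round trip preserves images to 8-bit precision and is reproducible", {
  spec <- phantom_spec(32L, 40L)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- generate_phantom_dataset(spec, n_studies = 4, out_dir = dir1, seed = 9)
  m2 <- generate_phantom_dataset(spec, n_studies = 4, out_dir = dir2, seed = 9)
  expect_equal(nrow(m1), 8L)
  # byte-identical regeneration
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$path[i], "raw", 1e6), readBin(m2$path[i], "raw", 1e6))
  }
  rt <- read_manifest(file.path(dir1, "manifest.csv"))
  expect_equal(rt$sample_id, m1$sample_id)
  loaded <- load_phantom_images(rt)
  fresh <- generate_phantom_dataset(spec, n_studies = 4, seed = 9)
  expect_lt(max(abs(loaded$image[[3]] - fresh$image[[3]])), 1 / 255)
  expect_identical(loaded$fov_mask[[3]], fresh$fov_mask[[3]])
})
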