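test_that("nearest-neighbour resize follows the floor-index rule", {
  img <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)  # [[0.1,0.2],[0.3,0.4]]
  expect_identical(resize_nearest(img, 2, 2), img)
  expect_equal(resize_nearest(img, 1, 1), matrix(0.1, 1, 1))
  expect_equal(resize_nearest(matrix(0.7, 1, 1), 2, 2), matrix(0.7, 2, 2))
  expect_error(resize_nearest(img, 0, 2), "positive")
})

test_that("resize introduces no intensity value absent from the source", {
  set.seed(10)
  for (i in 1:100) {
    h <- sample(3:20, 1); w <- sample(3:20, 1)
    img <- matrix(runif(h * w), h, w)
    out <- resize_nearest(img, sample(1:25, 1), sample(1:25, 1))
    expect_true(all(out %in% img))
  }
})

test_that("masking is an elementwise product, zero outside, and idempotent", {
  img <- matrix(c(0.5, 0.8), 1, 2)
  expect_equal(apply_mask(img, matrix(1, 1, 2)), img)
  expect_equal(apply_mask(img, matrix(0, 1, 2)), matrix(0, 1, 2))
  expect_equal(apply_mask(img, matrix(c(1, 0), 1, 2)), matrix(c(0.5, 0), 1, 2))
  set.seed(11)
  x <- matrix(runif(30), 5, 6)
  m <- matrix(rbinom(30, 1, 0.5), 5, 6)
  expect_identical(apply_mask(apply_mask(x, m), m), apply_mask(x, m))
  expect_error(apply_mask(x, matrix(1, 2, 2)), "shapes differ")
})

test_that("study splits are quota-exact, study-disjoint and whole-study", {
  man <- tibble::tibble(sample_id = sprintf("x%03d", 1:100),
                        path = NA_character_,
                        study_id = sprintf("s%03d", 1:100),
                        view_label = 0L, lvh_label = NA_integer_,
                        split = NA_character_)
  out <- split_by_study(man, c(train = 0.74, val = 0.11, test = 0.15), seed = 3)
  expect_equal(unname(table(out$split)[c("train", "val", "test")]),
               c(74L, 11L, 15L), ignore_attr = TRUE)

  # three studies, equal thirds: one whole study per split
  man3 <- tibble::tibble(sample_id = sprintf("y%d", 1:6), path = NA_character_,
                         study_id = rep(c("a", "b", "c"), each = 2),
                         view_label = 0L, lvh_label = NA_integer_,
                         split = NA_character_)
  out3 <- split_by_study(man3, c(1, 1, 1) / 3, seed = 1)
  expect_equal(as.integer(sort(table(out3$split))), c(2L, 2L, 2L))
  by_study <- tapply(out3$split, out3$study_id, function(s) length(unique(s)))
  expect_true(all(by_study == 1))

  expect_error(split_by_study(man3[1:2, ], c(1, 1, 1) / 3), "fewer studies")
  expect_error(split_by_study(man3, c(0.5, 0.4)), "sum to 1")
})

test_that("affine resampling shifts by whole pixels and augment is bounded", {
  img <- matrix(c(0, 0, 1, 0), 1, 4)
  expect_equal(echodl:::transform_image(img, 0, 0, 0.25 * 4), matrix(c(0, 0, 0, 1), 1, 4))
  expect_identical(augment(img, 0, 0), img)
  set.seed(12)
  a1 <- augment(matrix(runif(100), 10, 10), 10, 0.1)
  set.seed(12)
  a2 <- augment(matrix(runif(100), 10, 10), 10, 0.1)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("manifests round-trip losslessly with absent labels and extra columns", {
  man <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20), path = sprintf("img/%02d.png", 1:20),
    study_id = rep(sprintf("st%02d", 1:10), each = 2),
    view_label = rep(0:3, 5),
    lvh_label = ifelse(rep(0:3, 5) == 3L, rep(c(0L, 1L), 10), NA_integer_),
    split = rep(c("train", NA), 10), note = letters[1:20]
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back, man)
  # empty lvh field reads as absent, never 0
  expect_true(all(is.na(back$lvh_label[back$view_label != 3L])))

  dup <- man
  dup$sample_id[2] <- dup$sample_id[1]
  write_manifest(dup, path)
  expect_error(read_manifest(path), "duplicate")
  writeLines("sample_id,path\na,b", path)
  expect_error(read_manifest(path), "missing required columns")
})

test_that("intensity range conversion to the GAN boundary is invertible", {
  x <- matrix(seq(0, 1, length.out = 12), 3, 4)
  expect_equal(from_gan_range(to_gan_range(x)), x)
  expect_equal(range(to_gan_range(x)), c(-1, 1))
})
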