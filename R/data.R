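# Dataset handling: manifest I/O, study-level splits, nearest-neighbour
# resizing, masking, augmentation and intensity-range conversion.

MANIFEST_COLS <- c("sample_id", "path", "study_id", "view_label", "lvh_label", "split")

#' Read or write a CSV sample manifest
#'
#' The manifest dialect has header
#' `sample_id,path,study_id,view_label,lvh_label,split`; empty label fields
#' mean "absent" (`NA`), never 0. Unknown columns are preserved on a
#' round-trip. Labels are 0-based class indices.
#'
#' @param path File path.
#' @return `read_manifest()` returns a tibble of sample records.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing) > 0) {
    stop("manifest is missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$study_id <- as.character(df$study_id)
  df$split <- as.character(df$split)
  for (col in names(df)) {
    if (is.character(df[[col]])) df[[col]][df[[col]] == ""] <- NA_character_
  }
  for (col in c("view_label", "lvh_label")) {
    v <- df[[col]]
    v[v == ""] <- NA
    df[[col]] <- as.integer(v)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in manifest", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(MANIFEST_COLS, names(manifest))
  if (length(missing) > 0) {
    stop("manifest is missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- manifest[, c(MANIFEST_COLS, setdiff(names(manifest), MANIFEST_COLS))]
  out <- out[, !vapply(out, is.list, logical(1))]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign train/val/test splits at the study level
#'
#' Whole studies — never individual frames — are assigned to splits, so no
#' study straddles the train/test boundary. Studies are shuffled with the
#' seed and allocated by largest-remainder quota on study counts, which makes
#' the realised split sizes deterministic and exact at round numbers (100
#' single-frame studies at fractions 0.74/0.11/0.15 give exactly 74/11/15).
#'
#' @param manifest A manifest tibble with `study_id`.
#' @param fractions Numeric vector of train/val/test proportions summing to 1.
#' @param seed Integer seed for the study shuffle.
#' @return The manifest with its `split` column filled in.
#' @export
split_by_study <- function(manifest, fractions = c(train = 0.74, val = 0.11, test = 0.15),
                           seed = 1L) {
  if (any(is.na(manifest$study_id))) stop("every record needs a study_id", call. = FALSE)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")[seq_along(fractions)]
  studies <- unique(manifest$study_id)
  n <- length(studies)
  if (n < sum(fractions > 0)) {
    stop("fewer studies than nonzero-fraction splits", call. = FALSE)
  }
  # largest-remainder quota on study counts
  exact <- fractions * n
  base <- floor(exact)
  rem <- exact - base
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(rem, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  set.seed(seed)
  shuffled <- sample(studies)
  assignment <- rep(names(fractions), times = base)
  names(assignment) <- shuffled
  manifest$split <- unname(assignment[manifest$study_id])
  manifest
}

#' Nearest-neighbour resize
#'
#' Output pixel `(i, j)` copies source pixel
#' `(floor(i * H / target_h), floor(j * W / target_w))` (0-based indices):
#' pure index selection, so no intensity value absent from the source is ever
#' introduced.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param target_h,target_w Output size in pixels.
#' @return The resized matrix.
#' @export
resize_nearest <- function(image, target_h, target_w) {
  if (target_h <= 0 || target_w <= 0) stop("target dimensions must be positive", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  ri <- floor((seq_len(target_h) - 1) * h / target_h) + 1L
  ci <- floor((seq_len(target_w) - 1) * w / target_w) + 1L
  image[ri, ci, drop = FALSE]
}

#' Apply a binary mask to an image
#'
#' Elementwise product: pixels where the mask is 0 become exactly 0. This is
#' the masking step placed before classification, which removes metadata and
#' other off-sector clutter.
#'
#' @param image,mask Matrices of identical shape; `mask` is 0/1.
#' @return The masked image.
#' @export
apply_mask <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ", call. = FALSE)
  image * mask
}

# Nearest-neighbour affine resample: rotate by `angle` degrees about the
# image centre, then shift by (shift_r, shift_c) pixels; vacated pixels 0.
transform_image <- function(image, angle = 0, shift_r = 0, shift_c = 0) {
  h <- nrow(image); w <- ncol(image)
  shift_r <- round(shift_r); shift_c <- round(shift_c)
  th <- -angle * pi / 180  # inverse map
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  g <- grid_xy(h, w)
  yr <- g$y - shift_r - cy
  xr <- g$x - shift_c - cx
  sy <- round(cy + sin(th) * xr + cos(th) * yr)
  sx <- round(cx + cos(th) * xr - sin(th) * yr)
  ok <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
  out <- matrix(0, h, w)
  out[ok] <- image[cbind(sy[ok], sx[ok])]
  out
}

#' Random rotation/shift augmentation
#'
#' Draws a rotation angle uniform on `[-max_rotation, max_rotation]` degrees
#' and independent height/width shifts uniform on `[-max_shift, max_shift]`
#' of the respective dimension (rounded to whole pixels), then resamples with
#' nearest-neighbour interpolation, filling vacated pixels with 0 — black,
#' matching the echo background.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param max_rotation Maximum absolute rotation, degrees.
#' @param max_shift Maximum absolute shift as a proportion of each dimension.
#' @return The augmented image, same shape, values in `[0, 1]`.
#' @export
augment <- function(image, max_rotation = 10, max_shift = 0.1) {
  stopifnot(max_rotation >= 0, max_shift >= 0, max_shift < 1)
  if (max_rotation == 0 && max_shift == 0) return(image)
  ang <- stats::runif(1, -max_rotation, max_rotation)
  dr <- stats::runif(1, -max_shift, max_shift) * nrow(image)
  dc <- stats::runif(1, -max_shift, max_shift) * ncol(image)
  transform_image(image, ang, dr, dc)
}

# Stack a list of H x W matrices into the engine's (H, W, 1, N) layout.
stack_images <- function(images) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  x <- array(0, c(h, w, 1L, length(images)))
  for (i in seq_along(images)) x[, , 1L, i] <- images[[i]]
  x
}

#' Convert between the storage range [0,1] and the GAN range [-1,1]
#'
#' Images are stored in `[0, 1]`; the adversarial models exchange images in
#' `[-1, 1]` because the generator's final activation is Tanh.
#'
#' @param x Numeric array.
#' @return The rescaled array.
#' @export
to_gan_range <- function(x) 2 * x - 1

#' @rdname to_gan_range
#' @export
from_gan_range <- function(x) (x + 1) / 2
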