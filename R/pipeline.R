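# End-to-end routing: FoV segmentation -> masking -> view classification ->
# (for routed views) LV segmentation -> masking -> disease classification.

#' Bundle the models of the full classification pipeline
#'
#' @param fov_segmenter A trained `unet_model`/`unet_fit`, or a function
#'   `image -> mask` (ground-truth oracles and stubs plug in the same way).
#' @param view_classifier A `cnn_model`, a list of them (ensemble), or a
#'   function `list-of-images -> N x K probability matrix`.
#' @param routing Named list mapping view class index (as character, e.g.
#'   `"3"`) to a disease task name; views not in the table stop after view
#'   classification. Default routes only the LV-bearing class.
#' @param lv_segmenter Like `fov_segmenter`, for the left ventricle.
#' @param lvh_classifier Binary classifier (class 1 = LVH) as above.
#' @param seg_size `c(h, w)` input size of the segmenters.
#' @param clf_size `c(h, w)` input size of the view classifier.
#' @param lvh_size `c(h, w)` input size of the LVH classifier.
#' @return A `pipeline_bundle`.
#' @export
pipeline_bundle <- function(fov_segmenter, view_classifier, routing = list(),
                            lv_segmenter = NULL, lvh_classifier = NULL,
                            seg_size = c(120L, 160L), clf_size = seg_size,
                            lvh_size = clf_size) {
  for (task in names(routing)) {
    if (is.null(lv_segmenter) || is.null(lvh_classifier)) {
      stop("routing is configured but routed-stage models are missing", call. = FALSE)
    }
  }
  structure(list(fov_segmenter = fov_segmenter, view_classifier = view_classifier,
                 routing = routing, lv_segmenter = lv_segmenter,
                 lvh_classifier = lvh_classifier, seg_size = seg_size,
                 clf_size = clf_size, lvh_size = lvh_size),
            class = "pipeline_bundle")
}

seg_predict <- function(segmenter, image) {
  if (is.function(segmenter)) return(segmenter(image))
  predict_mask(segmenter, image)
}

clf_predict <- function(classifier, images) {
  if (is.function(classifier)) return(classifier(images))
  if (inherits(classifier, "cnn_model")) return(predict(classifier, images))
  if (inherits(classifier, "ssgan_fit")) return(predict(classifier, images))
  if (is.list(classifier)) return(ensemble_predict(classifier, images))
  stop("unsupported classifier object", call. = FALSE)
}

#' Run the full pipeline on one image
#'
#' Fixed stage order: resize to the segmenter's resolution, predict the FoV
#' mask and apply it, classify the masked image into a view (argmax with
#' ties broken toward the lowest class index), and — when the routing table
#' fires for the predicted view — predict the LV mask on the raw image,
#' apply it and run the disease classifier. Deterministic given the models.
#'
#' @param image Matrix in `[0, 1]` (any size; resized per stage).
#' @param bundle A [pipeline_bundle()].
#' @param keep_masks Retain the intermediate masks in the result.
#' @return A `pipeline_result` list: `view_pred`, `view_probs`, `lvh_pred`,
#'   `lvh_prob` (the latter two `NA` unless routing fired), and optionally
#'   `fov_mask`/`lv_mask`.
#' @export
run_pipeline <- function(image, bundle, keep_masks = FALSE) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  seg_in <- resize_nearest(image, bundle$seg_size[1], bundle$seg_size[2])
  fov <- seg_predict(bundle$fov_segmenter, seg_in)
  masked <- apply_mask(seg_in, fov)
  clf_in <- resize_nearest(masked, bundle$clf_size[1], bundle$clf_size[2])
  probs <- clf_predict(bundle$view_classifier, list(clf_in))
  view <- which.max(probs[1, ]) - 1L  # which.max takes the lowest index on ties

  res <- list(view_pred = view, view_probs = probs[1, ],
              lvh_pred = NA_integer_, lvh_prob = NA_real_)
  task <- bundle$routing[[as.character(view)]]
  if (!is.null(task)) {
    lv_in <- resize_nearest(image, bundle$seg_size[1], bundle$seg_size[2])
    lv <- seg_predict(bundle$lv_segmenter, lv_in)
    lv_masked <- apply_mask(lv_in, lv)
    lvh_in <- resize_nearest(lv_masked, bundle$lvh_size[1], bundle$lvh_size[2])
    p <- clf_predict(bundle$lvh_classifier, list(lvh_in))
    res$lvh_prob <- p[1, 2]
    res$lvh_pred <- as.integer(p[1, 2] > 0.5)
    if (keep_masks) res$lv_mask <- lv
  }
  if (keep_masks) res$fov_mask <- fov
  structure(res, class = "pipeline_result")
}

#' Run the pipeline over a manifest and write a results table
#'
#' One row per manifest row, order preserved. Re-running with the same
#' bundle is byte-identical because every stage is deterministic.
#'
#' @param manifest Manifest tibble; images are taken from the `image`
#'   list-column or loaded from `path`.
#' @param bundle A [pipeline_bundle()].
#' @param out_path Optional CSV destination.
#' @return A tibble with `sample_id`, `view_pred`, per-class
#'   `view_prob_<k>`, `lvh_pred`, `lvh_prob`.
#' @export
run_pipeline_batch <- function(manifest, bundle, out_path = NULL) {
  if (!"image" %in% names(manifest)) manifest <- load_phantom_images(manifest)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- run_pipeline(manifest$image[[i]], bundle)
    probs <- as.list(r$view_probs)
    names(probs) <- paste0("view_prob_", seq_along(probs) - 1L)
    tibble::as_tibble(c(list(sample_id = manifest$sample_id[i],
                             view_pred = r$view_pred),
                        probs,
                        list(lvh_pred = r$lvh_pred, lvh_prob = r$lvh_prob)))
  })
  out <- if (length(rows) == 0) {
    tibble::tibble(sample_id = character(0), view_pred = integer(0),
                   lvh_pred = integer(0), lvh_prob = numeric(0))
  } else {
    dplyr::bind_rows(rows)
  }
  if (!is.null(out_path)) utils::write.csv(out, out_path, row.names = FALSE, na = "")
  out
}
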