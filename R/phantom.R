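#' Specification for the synthetic echo phantom generator
#'
#' Describes the geometry and noise model of the synthetic ultrasound
#' phantoms that stand in for clinical echocardiogram stills: a bright,
#' speckled, sector-shaped field of view (FoV) on a black background, an
#' optional metadata band of glyph-like blocks above the sector, and a set of
#' dark intracardiac "chambers" whose arrangement defines the view class.
#' One designated class carries a left ventricle (LV) drawn as a bright
#' myocardial ring around a dark cavity; the ring's thickness (as a fraction
#' of the LV radius) is the sole feature separating hypertrophic (LVH) from
#' normal anatomy, so the disease signal is isolated by construction.
#'
#' @param height,width Image size in pixels.
#' @param n_view_classes Number of view classes `K` (2 to 15).
#' @param sector_half_angle Half-opening angle of the imaging sector, degrees.
#' @param chamber_layouts Per-class list of ellipse descriptors; defaults to
#'   [default_chamber_layouts()]. Each descriptor is a list of ellipses
#'   `list(cx, cy, ax, ay, rot, lv)` with centres as fractions of width and
#'   height, semi-axes as fractions of `min(height, width)`, rotation in
#'   degrees, and `lv = TRUE` on at most one ellipse of the LV-bearing class.
#' @param lv_class_index 0-based index of the class that carries an LV and
#'   admits an LVH label. Defaults to the last class.
#' @param wall_thickness_normal,wall_thickness_lvh Ranges `c(min, max)` of
#'   myocardial wall thickness as a fraction of the LV radius. The LVH
#'   minimum must exceed the normal maximum so the classes are separable.
#' @param speckle_strength Standard deviation of the unit-mean multiplicative
#'   speckle applied inside the sector; 0 disables speckle.
#' @param metadata_band Draw a band of bright glyph blocks along the top 8%
#'   of rows, outside the sector (the clutter FoV masking should remove).
#' @param frames_per_study Frames rendered per synthetic study; frames share
#'   the study's anatomy up to small per-frame jitter.
#' @param seed Optional integer stored with the spec and used as the default
#'   seed by [generate_phantom_dataset()].
#'
#' @return An object of class `phantom_spec`.
#' @seealso [render_phantom()], [generate_phantom_dataset()]
#' @export
phantom_spec <- function(height = 120L, width = 160L, n_view_classes = 4L,
                         sector_half_angle = 35,
                         chamber_layouts = default_chamber_layouts(),
                         lv_class_index = n_view_classes - 1L,
                         wall_thickness_normal = c(0.12, 0.20),
                         wall_thickness_lvh = c(0.30, 0.45),
                         speckle_strength = 0.45,
                         metadata_band = TRUE,
                         frames_per_study = 2L,
                         seed = NULL) {
  stopifnot(height >= 16, width >= 16, n_view_classes >= 2)
  if (n_view_classes > length(chamber_layouts)) {
    stop("n_view_classes exceeds the number of chamber layouts", call. = FALSE)
  }
  if (wall_thickness_lvh[1] <= wall_thickness_normal[2]) {
    stop("wall_thickness_lvh min must exceed wall_thickness_normal max ",
         "(classes must be separable by construction)", call. = FALSE)
  }
  fr <- c(wall_thickness_normal, wall_thickness_lvh)
  if (any(fr <= 0 | fr >= 1)) stop("wall thickness fractions must lie in (0,1)", call. = FALSE)
  if (speckle_strength < 0) stop("speckle_strength must be >= 0", call. = FALSE)
  if (lv_class_index < 0 || lv_class_index >= n_view_classes) {
    stop("lv_class_index out of range", call. = FALSE)
  }
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_view_classes = as.integer(n_view_classes),
    sector_half_angle = sector_half_angle,
    chamber_layouts = chamber_layouts,
    lv_class_index = as.integer(lv_class_index),
    wall_thickness_normal = wall_thickness_normal,
    wall_thickness_lvh = wall_thickness_lvh,
    speckle_strength = speckle_strength,
    metadata_band = isTRUE(metadata_band),
    frames_per_study = as.integer(frames_per_study),
    seed = seed
  ), class = "phantom_spec")
}

ellipse <- function(cx, cy, ax, ay, rot = 0, lv = FALSE) {
  list(cx = cx, cy = cy, ax = ax, ay = ay, rot = rot, lv = lv)
}

#' Default chamber layouts for up to 15 view classes
#'
#' The first four layouts mimic the coarse geometry of common echo views:
#' one large cavity (parasternal-long-axis-like), two side-by-side cavities,
#' three cavities, and a four-chamber arrangement whose upper-left chamber is
#' the LV. Classes 3 and 4 share sub-structure so they confuse under jitter
#' and speckle, mirroring the overlap between structurally similar clinical
#' views. Further layouts are procedural variations so the view classifier
#' can be stressed with up to 15 classes.
#'
#' @param n Number of layouts to return (max 15).
#' @return A list of per-class ellipse lists, as consumed by [phantom_spec()].
#' @export
default_chamber_layouts <- function(n = 15L) {
  base <- list(
    list(ellipse(0.50, 0.55, 0.30, 0.22, 20)),
    list(ellipse(0.38, 0.55, 0.14, 0.18), ellipse(0.62, 0.55, 0.14, 0.18)),
    list(ellipse(0.40, 0.42, 0.13, 0.12), ellipse(0.40, 0.68, 0.13, 0.12),
         ellipse(0.62, 0.55, 0.12, 0.16)),
    list(ellipse(0.40, 0.42, 0.15, 0.13, 10, lv = TRUE),
         ellipse(0.40, 0.68, 0.13, 0.11), ellipse(0.63, 0.42, 0.12, 0.11),
         ellipse(0.63, 0.68, 0.11, 0.10))
  )
  extra <- lapply(seq_len(11), function(k) {
    m <- (k - 1L) %% 4L + 1L  # 1..4 chambers per extra class
    phase <- 30 * k
    lapply(seq_len(m), function(j) {
      a <- (phase + 360 * (j - 1) / m) * pi / 180
      ellipse(0.5 + 0.13 * cos(a), 0.55 + 0.12 * sin(a),
              0.09 + 0.02 * ((k + j) %% 3), 0.08 + 0.015 * (j %% 2),
              rot = 15 * ((k + j) %% 5))
    })
  })
  c(base, extra)[seq_len(min(n, 15L))]
}

# Pixel-grid helpers --------------------------------------------------------

grid_xy <- function(h, w) {
  list(x = matrix(rep(seq_len(w), each = h), h, w),
       y = matrix(rep(seq_len(h), times = w), h, w))
}

ellipse_inside <- function(gx, gy, cx, cy, a, b, rot_deg) {
  th <- rot_deg * pi / 180
  dx <- gx - cx; dy <- gy - cy
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

# Study-level acquisition geometry: sector tilt/opening, per-chamber jitter,
# intensity gain and (for the LV class) the wall-thickness fraction.
draw_geometry <- function(spec, view_class, lvh) {
  layout <- spec$chamber_layouts[[view_class + 1L]]
  chambers <- lapply(layout, function(e) {
    e$cx <- e$cx + stats::rnorm(1, 0, 0.025)
    e$cy <- e$cy + stats::rnorm(1, 0, 0.025)
    sc <- stats::runif(1, 0.85, 1.15)
    e$ax <- e$ax * sc
    e$ay <- e$ay * stats::runif(1, 0.85, 1.15)
    e$rot <- e$rot + stats::runif(1, -10, 10)
    e
  })
  wall <- NA_real_
  if (!is.null(lvh) && !is.na(lvh)) {
    rng <- if (lvh == 1L) spec$wall_thickness_lvh else spec$wall_thickness_normal
    wall <- stats::runif(1, rng[1], rng[2])
  }
  list(
    chambers = chambers,
    half_angle = spec$sector_half_angle + stats::runif(1, -4, 4),
    tilt = stats::runif(1, -8, 8),
    gain = stats::runif(1, 0.75, 1.15),
    wall = wall
  )
}

# Small frame-to-frame perturbation within one study.
jitter_geometry <- function(geom) {
  geom$chambers <- lapply(geom$chambers, function(e) {
    e$cx <- e$cx + stats::rnorm(1, 0, 0.006)
    e$cy <- e$cy + stats::rnorm(1, 0, 0.006)
    e
  })
  geom$gain <- geom$gain * stats::runif(1, 0.97, 1.03)
  geom
}

render_from_geometry <- function(spec, geom, view_class, lvh) {
  h <- spec$height; w <- spec$width
  g <- grid_xy(h, w)
  s <- min(h, w)
  band_h <- if (spec$metadata_band) ceiling(0.08 * h) else 0L
  apex <- c(x = 0.5 * w, y = band_h + 2)
  radius <- 0.92 * (h - apex["y"])
  dx <- g$x - apex["x"]; dy <- g$y - apex["y"]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy) * 180 / pi        # 0 degrees points straight down
  sector <- (dy >= 0) & (r <= radius) & (abs(ang - geom$tilt) <= geom$half_angle)

  img <- matrix(0, h, w)
  img[sector] <- 0.55 * geom$gain
  lv_mask <- NULL
  for (e in geom$chambers) {
    inside <- ellipse_inside(g$x, g$y, e$cx * w, e$cy * h, e$ax * s, e$ay * s, e$rot)
    if (isTRUE(e$lv) && !is.na(geom$wall)) {
      cavity <- ellipse_inside(g$x, g$y, e$cx * w, e$cy * h,
                               e$ax * s * (1 - geom$wall),
                               e$ay * s * (1 - geom$wall), e$rot)
      img[inside & !cavity & sector] <- 0.85 * geom$gain  # myocardial ring
      img[cavity & sector] <- 0.06 * geom$gain
      lv_mask <- (inside & sector) * 1
    } else {
      img[inside & sector] <- 0.08 * geom$gain  # blood pool
    }
  }

  if (spec$speckle_strength > 0) {
    n_in <- sum(sector)
    shape <- 1 / spec$speckle_strength^2
    img[sector] <- img[sector] * stats::rgamma(n_in, shape = shape, rate = shape)
  }

  if (band_h > 0) {
    n_glyph <- sample(6:12, 1)
    for (i in seq_len(n_glyph)) {
      gw <- sample(2:6, 1)
      gh <- sample(1:max(1L, band_h - 1L), 1)
      x0 <- sample(seq_len(max(1L, w - gw)), 1)
      y0 <- sample(seq_len(max(1L, band_h - gh + 1L)), 1)
      img[y0:(y0 + gh - 1L), x0:(x0 + gw - 1L)] <- stats::runif(1, 0.6, 1)
    }
  }

  img <- pmin(pmax(img, 0), 1)
  structure(list(
    image = img,
    fov_mask = sector * 1,
    lv_mask = lv_mask,
    view_label = as.integer(view_class),
    lvh_label = if (is.null(lvh)) NA_integer_ else as.integer(lvh),
    study_id = NA_character_
  ), class = "phantom_sample")
}

#' Render one synthetic echo phantom
#'
#' Draws a fresh acquisition geometry (sector tilt and opening, chamber
#' jitter, intensity gain, wall thickness) from the current RNG stream and
#' renders the image together with its ground-truth field-of-view mask and,
#' for the LV-bearing class, the LV mask.
#'
#' @param spec A [phantom_spec()].
#' @param view_class 0-based view class index.
#' @param lvh 0/1 LVH status; must be supplied exactly when `view_class`
#'   equals the spec's `lv_class_index`.
#' @param seed Optional seed applied before drawing, for standalone
#'   reproducibility.
#' @return A `phantom_sample`: list with `image`, `fov_mask`, `lv_mask` (or
#'   `NULL`), `view_label`, `lvh_label`, `study_id`.
#' @export
render_phantom <- function(spec, view_class, lvh = NULL, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (view_class < 0 || view_class >= spec$n_view_classes) {
    stop("view_class must lie in 0..K-1", call. = FALSE)
  }
  is_lv <- view_class == spec$lv_class_index
  if (is_lv && is.null(lvh)) stop("lvh must be supplied for the LV-bearing class", call. = FALSE)
  if (!is_lv && !is.null(lvh)) stop("lvh supplied for a class without an LV", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  geom <- draw_geometry(spec, view_class, lvh)
  render_from_geometry(spec, geom, view_class, lvh)
}

#' Generate a phantom dataset with study grouping
#'
#' Studies are assigned view classes round-robin so classes stay balanced;
#' all frames of a study share one view class, one LVH status and one
#' underlying anatomy (with small frame-to-frame jitter). LVH status is
#' allocated by exact quota over the LV-view studies — `round(lvh_fraction *
#' n_lv_studies)` studies are hypertrophic — so small datasets carry the
#' intended roughly 4:1 normal:LVH imbalance exactly rather than on average.
#'
#' @param spec A [phantom_spec()].
#' @param n_studies Number of studies.
#' @param frames_per_study Frames per study (defaults to the spec's value).
#' @param lvh_fraction Fraction of LV-view studies labelled LVH.
#' @param out_dir If non-`NULL`, 8-bit grayscale PNGs (image and masks) are
#'   written under `out_dir` and the manifest is stored as
#'   `out_dir/manifest.csv`; otherwise images and masks are returned in
#'   list-columns.
#' @param seed Integer seed; defaults to the spec's `seed`.
#' @return A tibble manifest with columns `sample_id`, `path`, `study_id`,
#'   `view_label`, `lvh_label`, `split` plus either path columns
#'   (`fov_mask_path`, `lv_mask_path`) or list-columns (`image`, `fov_mask`,
#'   `lv_mask`).
#' @export
generate_phantom_dataset <- function(spec, n_studies, frames_per_study = spec$frames_per_study,
                                     lvh_fraction = 0.2, out_dir = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), n_studies >= 1)
  if (lvh_fraction < 0 || lvh_fraction > 1) stop("lvh_fraction must lie in [0,1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  k <- spec$n_view_classes
  views <- rep_len(0:(k - 1L), n_studies)
  lv_studies <- which(views == spec$lv_class_index)
  lvh_status <- rep(NA_integer_, n_studies)
  if (length(lv_studies) > 0) {
    n_lvh <- round(lvh_fraction * length(lv_studies))
    picked <- sample(lv_studies)[seq_len(n_lvh)]
    lvh_status[lv_studies] <- 0L
    lvh_status[picked] <- 1L
  }

  write_out <- !is.null(out_dir)
  if (write_out) {
    img_dir <- file.path(out_dir, "images")
    msk_dir <- file.path(out_dir, "masks")
    ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE) || dir.exists(img_dir)
    dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(msk_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }

  rows <- vector("list", n_studies * frames_per_study)
  ri <- 0L
  for (st in seq_len(n_studies)) {
    sid <- sprintf("S%04d", st)
    vc <- views[st]
    lv <- if (vc == spec$lv_class_index) lvh_status[st] else NULL
    geom <- draw_geometry(spec, vc, lv)
    for (f in seq_len(frames_per_study)) {
      fg <- if (f == 1L) geom else jitter_geometry(geom)
      sm <- render_from_geometry(spec, fg, vc, lv)
      sm$study_id <- sid
      id <- sprintf("%s_F%02d", sid, f)
      ri <- ri + 1L
      if (write_out) {
        ipath <- file.path(img_dir, paste0(id, ".png"))
        png::writePNG(sm$image, ipath)
        fpath <- file.path(msk_dir, paste0(id, "_fov.png"))
        png::writePNG(sm$fov_mask, fpath)
        lpath <- NA_character_
        if (!is.null(sm$lv_mask)) {
          lpath <- file.path(msk_dir, paste0(id, "_lv.png"))
          png::writePNG(sm$lv_mask, lpath)
        }
        rows[[ri]] <- tibble::tibble(
          sample_id = id, path = ipath, study_id = sid,
          view_label = sm$view_label, lvh_label = sm$lvh_label,
          split = NA_character_, fov_mask_path = fpath, lv_mask_path = lpath
        )
      } else {
        rows[[ri]] <- tibble::tibble(
          sample_id = id, path = NA_character_, study_id = sid,
          view_label = sm$view_label, lvh_label = sm$lvh_label,
          split = NA_character_,
          image = list(sm$image), fov_mask = list(sm$fov_mask),
          lv_mask = list(sm$lv_mask)
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (write_out) write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Load images (and masks, when present) referenced by a manifest
#'
#' @param manifest A manifest tibble with `path` (and optionally
#'   `fov_mask_path` / `lv_mask_path`) columns.
#' @return The manifest with `image`, `fov_mask`, `lv_mask` list-columns.
#' @export
load_phantom_images <- function(manifest) {
  read_gray <- function(p) {
    if (is.na(p)) return(NULL)
    x <- png::readPNG(p)
    if (length(dim(x)) == 3) x <- x[, , 1]
    x
  }
  manifest$image <- lapply(manifest$path, read_gray)
  if ("fov_mask_path" %in% names(manifest)) {
    manifest$fov_mask <- lapply(manifest$fov_mask_path, function(p) {
      m <- read_gray(p)
      if (!is.null(m)) (m > 0.5) * 1 else NULL
    })
  }
  if ("lv_mask_path" %in% names(manifest)) {
    manifest$lv_mask <- lapply(manifest$lv_mask_path, function(p) {
      m <- read_gray(p)
      if (!is.null(m)) (m > 0.5) * 1 else NULL
    })
  }
  manifest
}
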