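# Synthetic IVCM-like image generation.
#
# Four seeded texture recipes emulate the qualitative appearance of the four
# normal corneal layers seen in confocal microscopy:
#   epithelium   - Voronoi cell mosaic with dark borders, mid-bright cells
#   nerve_plexus - sparse smooth bright curvilinear fibers on a dark field
#   stroma       - sparse bright oval keratocyte nuclei on mid-gray ground
#   endothelium  - dense, regular, bright hexagonal mosaic with thin borders
# The recipes are parametric and fully deterministic in (layer, size, seed).

LAYER_CLASSES <- c("epithelium", "nerve_plexus", "stroma", "endothelium")
ANOMALY_KINDS <- c("bright_blob", "filament_tangle", "texture_dropout", "dark_patch")

#' Construct an IVCM image object
#'
#' @param pixels integer matrix, values in 0..255, both dims >= 32.
#' @param eye_id eye identifier string.
#' @param label "normal" or "anomalous".
#' @param layer_class one of the four corneal layer classes, or `NA`.
#' @param source_path originating file path, or `NA`.
#' @return An object of class `ivcm_image`.
#' @export
ivcm_image <- function(pixels, eye_id = NA_character_, label = "normal",
                       layer_class = NA_character_, source_path = NA_character_) {
  check_flag(is.matrix(pixels) && is.numeric(pixels), "`pixels` must be a numeric matrix")
  check_flag(nrow(pixels) >= 32 && ncol(pixels) >= 32,
             "image dimensions must be at least 32 x 32")
  check_flag(all(pixels >= 0 & pixels <= 255), "pixel values must lie in [0, 255]")
  check_flag(label %in% c("normal", "anomalous"), "label must be 'normal' or 'anomalous'")
  if (!is.na(layer_class)) {
    check_flag(layer_class %in% LAYER_CLASSES,
               paste("unknown layer_class; expected one of:", paste(LAYER_CLASSES, collapse = ", ")))
  }
  structure(list(pixels = matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels)),
                 eye_id = eye_id, label = label, layer_class = layer_class,
                 source_path = source_path),
            class = "ivcm_image")
}

#' @export
print.ivcm_image <- function(x, ...) {
  cat(sprintf("<ivcm_image %dx%d  eye=%s  label=%s  layer=%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$eye_id, x$label, x$layer_class))
  invisible(x)
}

# Two-nearest-site Voronoi fields used by the mosaic textures. Returns the
# nearest-site index and the border strength sqrt(d2) - sqrt(d1) per pixel.
voronoi_field <- function(size, pts) {
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  d1 <- matrix(Inf, size, size)
  d2 <- matrix(Inf, size, size)
  cell <- matrix(1L, size, size)
  for (i in seq_len(nrow(pts))) {
    d <- (yy - pts[i, 1])^2 + (xx - pts[i, 2])^2
    closer1 <- d < d1
    d2 <- pmin(d2, ifelse(closer1, d1, d))
    cell[closer1] <- i
    d1 <- pmin(d1, d)
  }
  list(cell = cell, border = sqrt(d2) - sqrt(d1))
}

# Smooth low-frequency field: coarse Gaussian grid upsampled bilinearly.
smooth_field <- function(size, coarse, sd) {
  g <- matrix(stats::rnorm(coarse * coarse, 0, sd), coarse, coarse)
  m <- bilinear_matrix(coarse, coarse, size, size)
  matrix(m %*% as.vector(t(g)), size, size, byrow = TRUE)
}

texture_epithelium <- function(size) {
  n <- max(12L, round(size^2 / 170))
  pts <- cbind(stats::runif(n, 1, size), stats::runif(n, 1, size))
  v <- voronoi_field(size, pts)
  vals <- stats::rnorm(n, 150, 18)
  img <- matrix(vals[v$cell], size, size)
  dark <- exp(-(v$border / 1.6)^2)
  img <- img * (1 - 0.68 * dark)
  img + stats::rnorm(size^2, 0, 7)
}

texture_endothelium <- function(size) {
  sp <- size / 9
  rows <- seq(-sp, size + sp, by = sp * 0.87)
  pts <- do.call(rbind, lapply(seq_along(rows), function(r) {
    off <- if (r %% 2 == 0) sp / 2 else 0
    xs <- seq(-sp, size + sp, by = sp) + off
    cbind(rows[r], xs)
  }))
  pts <- pts + matrix(stats::rnorm(length(pts), 0, sp * 0.07), nrow(pts), 2)
  v <- voronoi_field(size, pts)
  vals <- stats::rnorm(nrow(pts), 178, 7)
  img <- matrix(vals[v$cell], size, size)
  dark <- exp(-(v$border / 1.0)^2)
  img <- img * (1 - 0.5 * dark)
  img + stats::rnorm(size^2, 0, 5)
}

texture_stroma <- function(size) {
  img <- 98 + smooth_field(size, 8L, 9) + matrix(stats::rnorm(size^2, 0, 6), size, size)
  nk <- max(4L, round(size^2 / 480))
  for (i in seq_len(nk)) {
    cy <- stats::runif(1, 3, size - 2); cx <- stats::runif(1, 3, size - 2)
    a <- size * stats::runif(1, 0.025, 0.045)  # major axis sd, px
    b <- a * stats::runif(1, 0.45, 0.7)
    th <- stats::runif(1, 0, pi)
    amp <- stats::runif(1, 55, 95)
    w <- ceiling(3 * a)
    ys <- max(1, floor(cy - w)):min(size, ceiling(cy + w))
    xs <- max(1, floor(cx - w)):min(size, ceiling(cx + w))
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    u <- dy * cos(th) + dx * sin(th)
    vv <- -dy * sin(th) + dx * cos(th)
    img[ys, xs] <- img[ys, xs] + amp * exp(-0.5 * ((u / a)^2 + (vv / b)^2))
  }
  img
}

texture_nerve_plexus <- function(size) {
  img <- 32 + matrix(stats::rnorm(size^2, 0, 5), size, size)
  n_fib <- 4L + size %/% 32L
  for (f in seq_len(n_fib)) {
    y <- stats::runif(1, 1, size); x <- stats::runif(1, 1, size)
    ang <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 150, 210)
    len <- round(1.6 * size)
    turns <- stats::rnorm(len, 0, 0.07)
    for (s in seq_len(len)) {
      ang <- ang + turns[s]
      y <- y + sin(ang); x <- x + cos(ang)
      if (y < 2 || y > size - 1 || x < 2 || x > size - 1) {
        ang <- ang + pi / 2  # turn away from the border
        y <- clip(y, 2, size - 1); x <- clip(x, 2, size - 1)
      }
      iy <- round(y); ix <- round(x)
      ys <- max(1, iy - 2):min(size, iy + 2)
      xs <- max(1, ix - 2):min(size, ix + 2)
      dd <- outer((ys - y)^2, rep(1, length(xs))) +
            outer(rep(1, length(ys)), (xs - x)^2)
      patch <- amp * exp(-dd / (2 * 0.8^2))
      img[ys, xs] <- pmax(img[ys, xs], patch)
    }
  }
  img
}

#' Generate one synthetic corneal-layer texture
#'
#' Deterministic in `(layer, size, seed)`; the four classes are statistically
#' separable by first-order intensity and edge statistics, emulating the
#' distinct normal morphology of each corneal layer.
#'
#' @param layer one of `"epithelium"`, `"nerve_plexus"`, `"stroma"`,
#'   `"endothelium"`.
#' @param size image side length in pixels (>= 32).
#' @param seed non-negative integer seed.
#' @return An [ivcm_image()] labeled `"normal"` with `layer_class = layer`.
#' @export
#' @examples
#' img <- gen_layer_texture("stroma", 64, seed = 1)
gen_layer_texture <- function(layer, size, seed) {
  check_flag(is.character(layer) && length(layer) == 1L && layer %in% LAYER_CLASSES,
             paste("unknown layer; expected one of:", paste(LAYER_CLASSES, collapse = ", ")))
  size <- check_count(size, min = 32L)
  seed <- check_count(seed, min = 0L)
  px <- with_seed(derive_seed(seed, match(layer, LAYER_CLASSES)), {
    switch(layer,
           epithelium   = texture_epithelium(size),
           nerve_plexus = texture_nerve_plexus(size),
           stroma       = texture_stroma(size),
           endothelium  = texture_endothelium(size))
  })
  ivcm_image(clip(round(px), 0, 255), label = "normal", layer_class = layer)
}

#' Fraction of strong-gradient pixels
#'
#' Central-difference gradient magnitude thresholded at a fixed value; used as
#' a simple ridge/edge density feature for texture statistics.
#'
#' @param img an [ivcm_image()] or numeric matrix.
#' @param threshold gradient-magnitude threshold on the 0-255 scale.
#' @return Fraction of interior pixels whose gradient magnitude exceeds
#'   `threshold`.
#' @export
edge_fraction <- function(img, threshold = 40) {
  px <- if (inherits(img, "ivcm_image")) img$pixels else img
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  h <- nrow(px); w <- ncol(px)
  gy <- (px[3:h, 2:(w - 1)] - px[1:(h - 2), 2:(w - 1)]) / 2
  gx <- (px[2:(h - 1), 3:w] - px[2:(h - 1), 1:(w - 2)]) / 2
  mean(sqrt(gx^2 + gy^2) > threshold)
}

#' Specify a lesion to inject
#'
#' @param kind one of `"bright_blob"`, `"filament_tangle"`,
#'   `"texture_dropout"`, `"dark_patch"`.
#' @param severity target lesion area as a fraction of image area, in (0, 0.5].
#' @param seed non-negative integer seed.
#' @return An `anomaly_spec` object.
#' @export
anomaly_spec <- function(kind, severity, seed) {
  check_flag(is.character(kind) && length(kind) == 1L && kind %in% ANOMALY_KINDS,
             paste("unknown anomaly kind; expected one of:", paste(ANOMALY_KINDS, collapse = ", ")))
  check_flag(is.numeric(severity) && length(severity) == 1L &&
               severity > 0 && severity <= 0.5,
             "`severity` must lie in (0, 0.5]")
  seed <- check_count(seed, min = 0L)
  structure(list(kind = kind, severity = severity, seed = seed),
            class = "anomaly_spec")
}

# Elliptical lesion footprint of area ~ severity * H * W, placed fully inside
# the image whenever geometry allows so the realized area tracks the target.
lesion_mask <- function(h, w, severity) {
  r <- sqrt(severity * h * w / pi)
  a <- r * stats::runif(1, 0.85, 1.18)
  b <- r^2 / a
  th <- stats::runif(1, 0, pi)
  ext <- max(a, b) + 1
  cy <- if (2 * ext < h) stats::runif(1, ext, h - ext) else h / 2
  cx <- if (2 * ext < w) stats::runif(1, ext, w - ext) else w / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- yy * cos(th) + xx * sin(th)
  v <- -yy * sin(th) + xx * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Inject a synthetic lesion into a normal image
#'
#' The returned image differs from the input exactly on the returned mask
#' (pixels outside the mask are copied unchanged; every pixel inside the mask
#' is guaranteed to change), and the mask area is commensurate with
#' `spec$severity`.
#'
#' @param img an [ivcm_image()].
#' @param spec an [anomaly_spec()].
#' @return A list with elements `image` (an `ivcm_image` labeled
#'   `"anomalous"`) and `mask` (logical matrix, the ground-truth lesion
#'   support).
#' @export
inject_anomaly <- function(img, spec) {
  check_flag(inherits(img, "ivcm_image"), "`img` must be an ivcm_image")
  check_flag(inherits(spec, "anomaly_spec"), "`spec` must be an anomaly_spec")
  old <- matrix(as.numeric(img$pixels), nrow(img$pixels), ncol(img$pixels))
  h <- nrow(old); w <- ncol(old)
  out <- with_seed(derive_seed(spec$seed, match(spec$kind, ANOMALY_KINDS), h, w), {
    mask <- lesion_mask(h, w, spec$severity)
    new <- old
    if (spec$kind == "bright_blob") {
      new[mask] <- 0.3 * old[mask] + 0.7 * 235 + stats::rnorm(sum(mask), 0, 6)
    } else if (spec$kind == "dark_patch") {
      new[mask] <- 0.22 * old[mask] + stats::rnorm(sum(mask), 0, 3)
    } else if (spec$kind == "texture_dropout") {
      new[mask] <- mean(old[mask]) + stats::rnorm(sum(mask), 0, 2)
    } else { # filament_tangle: darkened bed plus dense bright strokes
      new[mask] <- 0.5 * old[mask]
      r <- sqrt(spec$severity * h * w / pi)
      idx <- which(mask, arr.ind = TRUE)
      cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
      for (f in seq_len(6)) {
        y <- cy; x <- cx; ang <- stats::runif(1, 0, 2 * pi)
        for (s in seq_len(round(4 * r))) {
          ang <- ang + stats::rnorm(1, 0, 0.25)
          y2 <- y + sin(ang); x2 <- x + cos(ang)
          iy <- round(y2); ix <- round(x2)
          if (iy < 1 || iy > h || ix < 1 || ix > w || !mask[iy, ix]) {
            ang <- ang + pi * stats::runif(1, 0.4, 0.6)
            next
          }
          y <- y2; x <- x2
          new[iy, ix] <- 225
        }
      }
    }
    list(new = new, mask = mask)
  })
  new <- clip(round(out$new), 0, 255)
  # enforce exact support: every masked pixel must actually differ
  same <- out$mask & (new == img$pixels)
  new[same] <- ifelse(img$pixels[same] <= 253, img$pixels[same] + 2L,
                      img$pixels[same] - 2L)
  res <- ivcm_image(new, eye_id = img$eye_id, label = "anomalous",
                    layer_class = NA_character_, source_path = img$source_path)
  list(image = res, mask = out$mask)
}

#' Build a seeded synthetic cohort organized by eye
#'
#' Eyes are wholly normal or wholly anomalous; normal eyes cycle through the
#' four layer classes so the cohort presents the full multi-class normality
#' challenge. `floor(anomalous_eye_fraction * n_eyes)` eyes are lesioned, and
#' each anomalous image carries a ground-truth lesion mask.
#'
#' @param n_eyes number of eyes (>= 2).
#' @param images_per_eye images per eye (>= 1).
#' @param anomalous_eye_fraction fraction of eyes that are anomalous, in
#'   \[0, 1\].
#' @param size image side length in pixels.
#' @param seed master integer seed; all randomness derives from it.
#' @return An `ivcm_cohort`: list with `images` (named list of
#'   [ivcm_image()]), `masks` (named list of logical matrices for anomalous
#'   images), and `manifest` (data.frame with columns path, eye_id, label,
#'   layer_class, split).
#' @export
build_synthetic_cohort <- function(n_eyes, images_per_eye,
                                   anomalous_eye_fraction = 0.0,
                                   size = 64, seed = 1) {
  n_eyes <- check_count(n_eyes, min = 2L)
  images_per_eye <- check_count(images_per_eye, min = 1L)
  check_flag(is.numeric(anomalous_eye_fraction) && length(anomalous_eye_fraction) == 1L &&
               anomalous_eye_fraction >= 0 && anomalous_eye_fraction <= 1,
             "`anomalous_eye_fraction` must lie in [0, 1]")
  size <- check_count(size, min = 32L)
  seed <- check_count(seed, min = 0L)

  n_anom <- floor(anomalous_eye_fraction * n_eyes)
  anom_eyes <- if (n_anom > 0) {
    with_seed(derive_seed(seed, 999983L), sample.int(n_eyes, n_anom))
  } else integer(0)

  images <- list(); masks <- list()
  rows <- vector("list", n_eyes * images_per_eye)
  k <- 0L
  for (e in seq_len(n_eyes)) {
    eye_id <- sprintf("eye%03d", e)
    anom <- e %in% anom_eyes
    for (i in seq_len(images_per_eye)) {
      k <- k + 1L
      path <- sprintf("%s_img%03d.png", eye_id, i)
      layer <- LAYER_CLASSES[((i - 1L + e) %% 4L) + 1L]
      img_seed <- derive_seed(seed, e, i)
      base <- gen_layer_texture(layer, size, img_seed)
      base$eye_id <- eye_id; base$source_path <- path
      if (anom) {
        kind <- ANOMALY_KINDS[((i - 1L + e) %% 4L) + 1L]
        sev <- with_seed(derive_seed(img_seed, 7L), stats::runif(1, 0.05, 0.2))
        inj <- inject_anomaly(base, anomaly_spec(kind, sev, derive_seed(img_seed, 11L)))
        inj$image$source_path <- path
        images[[path]] <- inj$image
        masks[[path]] <- inj$mask
        rows[[k]] <- data.frame(path = path, eye_id = eye_id, label = "anomalous",
                                layer_class = "", split = "unassigned",
                                stringsAsFactors = FALSE)
      } else {
        images[[path]] <- base
        rows[[k]] <- data.frame(path = path, eye_id = eye_id, label = "normal",
                                layer_class = layer, split = "unassigned",
                                stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(images = images, masks = masks,
                 manifest = do.call(rbind, rows)),
            class = "ivcm_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes 8-bit grayscale PNGs, lesion masks as `<stem>.mask.png`, and
#' `manifest.csv`.
#'
#' @param cohort an `ivcm_cohort` from [build_synthetic_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  check_flag(inherits(cohort, "ivcm_cohort"), "`cohort` must be an ivcm_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (path in names(cohort$images)) {
    png::writePNG(cohort$images[[path]]$pixels / 255, file.path(dir, path))
    if (path %in% names(cohort$masks)) {
      mk <- sub("\\.png$", ".mask.png", path)
      png::writePNG(cohort$masks[[path]] * 1.0, file.path(dir, mk))
    }
  }
  mpath <- file.path(dir, "manifest.csv")
  write_manifest(cohort$manifest, mpath)
  invisible(mpath)
}
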