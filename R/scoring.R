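# Inference: per-token error maps, calibrated 0-255 image scores, threshold
# classification, and blue-to-red explainability overlays.

#' Per-token reconstruction error map
#'
#' `raw[h, w]` is the L2 norm over the hidden dimension of
#' `f_org - f_rec` at that token; `scaled_8bit` maps it through the stored
#' calibration: `clip(raw / scale_value, 0, 1) * 255`.
#'
#' @param f_org,f_rec `(H*W) x D` fused feature maps of identical shape.
#' @param calib calibration list with positive `scale_value` (as stored by
#'   [calibrate_score_scale()]).
#' @return An `error_map`: list with matrices `raw` and `scaled_8bit`
#'   (`H x W`) plus the grid dims.
#' @export
error_map <- function(f_org, f_rec, calib) {
  check_flag(all(dim(f_org) == dim(f_rec)), "f_org and f_rec must have identical shape")
  check_flag(is.list(calib) && is.numeric(calib$scale_value) && calib$scale_value > 0,
             "`calib` must carry a positive scale_value")
  gh <- attr(f_org, "grid_h") %||% nrow(f_org)
  gw <- attr(f_org, "grid_w") %||% 1L
  raw <- sqrt(rowSums((unclass(f_org) - unclass(f_rec))^2))
  scaled <- clip(raw / calib$scale_value, 0, 1) * 255
  structure(list(raw = matrix(raw, gh, gw, byrow = TRUE),
                 scaled_8bit = matrix(scaled, gh, gw, byrow = TRUE),
                 grid = c(gh, gw)),
            class = "error_map")
}

#' Raw image-level anomaly score
#'
#' The arithmetic mean of the calibrated 8-bit token errors; lies in
#' \[0, 255\].
#'
#' @param em an [error_map()].
#' @return Scalar raw score `S`.
#' @export
image_score <- function(em) {
  check_flag(inherits(em, "error_map"), "`em` must be an error_map")
  mean(em$scaled_8bit)
}

#' Normalize a raw anomaly score to \[0, 1\]
#'
#' Two conventions are supported. `"ascending"` (the default) maps higher
#' raw scores to higher normalized scores, `(S - Smin) / (Smax - Smin)`,
#' matching the convention that anomalous images score high. `"descending"`
#' is the inverted variant `(Smax - S) / (Smax - Smin)`, which maps the
#' upper calibration bound to 0. Both are clipped to \[0, 1\]; for unclipped
#' scores the two modes sum to exactly 1.
#'
#' @param s raw score (vectorized).
#' @param smax,smin calibration bounds, `smax > smin`; conventionally the
#'   extremes of the raw scores over the internal validation set.
#' @param mode `"ascending"` or `"descending"`.
#' @return Normalized score(s) in \[0, 1\].
#' @export
normalize_score <- function(s, smax, smin, mode = c("ascending", "descending")) {
  mode <- match.arg(mode)
  check_flag(is.numeric(smax) && is.numeric(smin) && smax > smin,
             "`smax` must exceed `smin`")
  z <- if (mode == "ascending") (s - smin) / (smax - smin)
       else (smax - s) / (smax - smin)
  clip(z, 0, 1)
}

#' Classify a raw score against a threshold
#'
#' An image is called anomalous when its raw score strictly exceeds the
#' threshold (a score equal to the threshold stays normal).
#'
#' @param s_raw raw score(s).
#' @param threshold finite decision threshold on the raw scale.
#' @return `"anomalous"` or `"normal"` (vectorized).
#' @export
classify <- function(s_raw, threshold) {
  check_flag(is.numeric(threshold) && length(threshold) == 1L && is.finite(threshold),
             "`threshold` must be a single finite number")
  ifelse(s_raw > threshold, "anomalous", "normal")
}

# 256-entry blue -> cyan -> yellow -> red lookup table, deterministic.
anomaly_colormap <- function() {
  anchors <- rbind(c(0, 0, 255), c(0, 255, 255), c(255, 255, 0), c(255, 0, 0))
  pos <- c(0, 85, 170, 255)
  t(vapply(0:255, function(i) {
    j <- findInterval(i, pos, rightmost.closed = TRUE)
    w <- (i - pos[j]) / (pos[j + 1] - pos[j])
    (1 - w) * anchors[j, ] + w * anchors[j + 1, ]
  }, numeric(3)))
}

#' Explainable anomaly heatmap overlay
#'
#' Upsamples the calibrated 8-bit error map bilinearly to the original image
#' dimensions, maps it through a fixed blue-to-red gradient (high error red,
#' low error blue), and alpha-blends it onto the original grayscale image.
#'
#' @param em an [error_map()].
#' @param original the original [ivcm_image()] (or pixel matrix).
#' @param alpha blend weight of the colormap layer, in \[0, 1\].
#' @return `H x W x 3` array in \[0, 1\], suitable for [png::writePNG()].
#' @export
anomaly_heatmap <- function(em, original, alpha = 0.5) {
  check_flag(inherits(em, "error_map"), "`em` must be an error_map")
  check_flag(is.numeric(alpha) && length(alpha) == 1L && alpha >= 0 && alpha <= 1,
             "`alpha` must lie in [0, 1]")
  px <- if (inherits(original, "ivcm_image")) original$pixels else original
  h <- nrow(px); w <- ncol(px)
  up <- bilinear_matrix(em$grid[1], em$grid[2], h, w) %*% as.vector(t(em$scaled_8bit))
  idx <- clip(floor(up), 0, 255) + 1
  lut <- anomaly_colormap() / 255
  cmap <- array(lut[idx, ], dim = c(w, h, 3))     # row-major vector -> (w,h)
  cmap <- aperm(cmap, c(2, 1, 3))
  gray <- array(rep(as.numeric(px) / 255, 3), dim = c(h, w, 3))
  (1 - alpha) * gray + alpha * cmap
}

#' Score one image with a calibrated model
#'
#' @param model a trained, calibrated [ad_model()].
#' @param img an [ivcm_image()].
#' @return List with `f_org`, `f_rec`, `em` (the [error_map()]) and `s_raw`.
#' @export
score_image <- function(model, img) {
  check_flag(!is.null(model$calibration),
             "model is not calibrated; run calibrate_score_scale() first")
  fw <- model_forward(model, model_pyramid(model, img))
  em <- error_map(fw$f_org, fw$f_rec, model$calibration)
  list(f_org = fw$f_org, f_rec = fw$f_rec, em = em, s_raw = image_score(em))
}

#' Score a set of images
#'
#' @param model a trained, calibrated [ad_model()].
#' @param images list of [ivcm_image()] objects.
#' @param bounds optional `c(smax, smin)` normalization bounds; defaults to
#'   the max/min raw score over `images`.
#' @param threshold optional decision threshold; when supplied a
#'   `predicted_label` column is added.
#' @param mode normalization mode, see [normalize_score()].
#' @return data.frame: path, eye_id, label, S_raw, S_norm (and
#'   predicted_label when `threshold` is given).
#' @export
score_images <- function(model, images, bounds = NULL, threshold = NULL,
                         mode = "ascending") {
  s <- vapply(images, function(im) score_image(model, im)$s_raw, numeric(1))
  if (is.null(bounds)) bounds <- c(max(s), min(s))
  if (bounds[1] <= bounds[2]) bounds <- c(bounds[2] + 1, bounds[2])
  out <- data.frame(
    path = vapply(images, function(im) im$source_path %||% NA_character_, character(1)),
    eye_id = vapply(images, function(im) im$eye_id %||% NA_character_, character(1)),
    label = vapply(images, function(im) im$label, character(1)),
    S_raw = s,
    S_norm = normalize_score(s, bounds[1], bounds[2], mode),
    stringsAsFactors = FALSE)
  if (!is.null(threshold)) out$predicted_label <- classify(s, threshold)
  rownames(out) <- NULL
  out
}
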