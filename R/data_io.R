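# Manifest handling, eye-grouped splitting, and image preprocessing.
#
# IVCM devices export 8-bit grayscale frames (nominally 384 x 384 after the
# peripheral border and overlaid text are cropped away). The model consumes
# RGB input, so the single gray channel is triplicated; images are never
# resampled, which would alter the texture statistics the detector relies on.

#' Load a grayscale image as a triplicated-channel RGB array
#'
#' Reads a PNG or TIFF file, checks it is grayscale (or has three identical
#' channels), and returns an `H x W x 3` array whose channels are bitwise
#' identical copies of the gray channel, on the 0-255 scale.
#'
#' @param path path to a PNG or TIFF file.
#' @return Numeric array `H x W x 3`, values in 0..255.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop(structure(class = c("ivcmad_io_error", "error", "condition"),
                   list(message = sprintf("cannot read image: %s", path), call = NULL)))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop_invalid(sprintf("unsupported image format '.%s' (PNG and TIFF are supported)", ext)))
  gray <- if (length(dim(raw)) == 2L) {
    raw
  } else {
    nc <- dim(raw)[3]
    chans <- lapply(seq_len(min(nc, 3L)), function(k) raw[, , k])
    for (k in seq_along(chans)[-1]) {
      if (!identical(chans[[1]], chans[[k]])) {
        stop_invalid("multi-channel input with unequal channels is not a grayscale image")
      }
    }
    chans[[1]]
  }
  g <- round(gray * 255)
  array(rep(g, 3L), dim = c(nrow(g), ncol(g), 3L))
}

#' Crop a fixed border box out of an image
#'
#' Pixels are copied, never resampled. Used to remove the peripheral border
#' and overlaid device text from raw frames.
#'
#' @param img an [ivcm_image()], a matrix, or an `H x W x 3` array.
#' @param box integer vector `(top, left, height, width)` (1-based top/left).
#' @return Same type as the input, cropped to `height x width`.
#' @export
crop_border <- function(img, box) {
  check_flag(is.numeric(box) && length(box) == 4L, "`box` must be (top, left, height, width)")
  top <- box[1]; left <- box[2]; height <- box[3]; width <- box[4]
  check_flag(height >= 1 && width >= 1, "box height and width must be >= 1")
  px <- if (inherits(img, "ivcm_image")) img$pixels else img
  h <- dim(px)[1]; w <- dim(px)[2]
  check_flag(top >= 1 && left >= 1 && top + height - 1 <= h && left + width - 1 <= w,
             "box exceeds image bounds")
  rows <- top:(top + height - 1); cols <- left:(left + width - 1)
  if (inherits(img, "ivcm_image")) {
    out <- img
    out$pixels <- px[rows, cols, drop = FALSE]
    out
  } else if (length(dim(px)) == 3L) {
    px[rows, cols, , drop = FALSE]
  } else {
    px[rows, cols, drop = FALSE]
  }
}

#' Read a manifest CSV
#'
#' @param path CSV with header `path,eye_id,label,layer_class,split`.
#' @return data.frame of manifest records.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("path", "eye_id", "label", "layer_class", "split")
  check_flag(all(need %in% names(m)),
             paste("manifest must have columns:", paste(need, collapse = ", ")))
  check_flag(all(m$label %in% c("normal", "anomalous")),
             "manifest labels must be 'normal' or 'anomalous'")
  m[, need]
}

#' Write a manifest CSV
#'
#' @param records manifest data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(records, path) {
  utils::write.csv(records[, c("path", "eye_id", "label", "layer_class", "split")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Eye-grouped train/validation split
#'
#' All images of one eye land in a single split, preventing leakage between
#' training and evaluation. Only normal eyes are eligible for training;
#' anomalous eyes always go to the validation side. Normal eyes are shuffled
#' by `seed`, ordered by descending image count, and assigned greedily to the
#' side whose image-count deficit against the target fraction is larger, so
#' the image-level train share approximates `train_fraction` as closely as an
#' eye-level partition allows.
#'
#' @param records manifest data.frame (columns path, eye_id, label, ...).
#' @param train_fraction target fraction of normal images in train, in (0,1).
#' @param seed integer seed for the eye shuffle.
#' @return A `split_manifest`: list with `records` (with the `split` column
#'   filled with `"train"`/`"val"`), `train_fraction`, `achieved_fraction`,
#'   and `seed`.
#' @export
split_by_eye <- function(records, train_fraction = 0.85, seed = 1) {
  check_flag(is.data.frame(records) && all(c("eye_id", "label") %in% names(records)),
             "`records` must be a manifest data.frame")
  check_flag(is.numeric(train_fraction) && length(train_fraction) == 1L &&
               train_fraction > 0 && train_fraction < 1,
             "`train_fraction` must lie in (0, 1)")
  normal_eyes <- unique(records$eye_id[records$label == "normal"])
  mixed <- intersect(normal_eyes, unique(records$eye_id[records$label == "anomalous"]))
  check_flag(length(mixed) == 0L,
             "eyes with both normal and anomalous images cannot be split")
  check_flag(length(normal_eyes) >= 2L, "need at least 2 normal eyes to split")

  counts <- table(records$eye_id[records$label == "normal"])
  eyes <- with_seed(derive_seed(seed, 17L), sample(normal_eyes))
  eyes <- eyes[order(-as.integer(counts[eyes]))]  # stable: keeps shuffle order within ties

  total <- sum(counts)
  target_train <- train_fraction * total
  target_val <- total - target_train
  t_n <- 0; v_n <- 0
  side <- character(length(eyes))
  for (i in seq_along(eyes)) {
    if ((target_train - t_n) >= (target_val - v_n)) {
      side[i] <- "train"; t_n <- t_n + as.integer(counts[eyes[i]])
    } else {
      side[i] <- "val"; v_n <- v_n + as.integer(counts[eyes[i]])
    }
  }
  split <- ifelse(records$label == "anomalous", "val",
                  side[match(records$eye_id, eyes)])
  out <- records
  out$split <- split
  structure(list(records = out,
                 train_fraction = train_fraction,
                 achieved_fraction = t_n / total,
                 seed = seed),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  tb <- table(x$records$split, x$records$label)
  cat(sprintf("<split_manifest  target train fraction %.3f, achieved %.4f>\n",
              x$train_fraction, x$achieved_fraction))
  print(tb)
  invisible(x)
}

#' Records of the training split (normal-only, hard-checked)
#'
#' @param split a `split_manifest`.
#' @return data.frame of train records. Errors if any anomalous record would
#'   enter training; anomalous records are never silently filtered.
#' @export
train_records <- function(split) {
  check_flag(inherits(split, "split_manifest"), "`split` must be a split_manifest")
  tr <- split$records[split$records$split == "train", , drop = FALSE]
  if (any(tr$label != "normal")) {
    stop_invalid("training split contains anomalous records; refusing to proceed",
                 class = "ivcmad_train_purity_error")
  }
  tr
}
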