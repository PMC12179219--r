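# Frozen convolutional backbone producing the multi-scale feature pyramid.
#
# Two profiles:
#   * efficientnet_b3_pretrained - the full-scale backbone named in the model
#     configuration. Pretrained ImageNet weights are not bundled with this
#     package, so feature extraction with it errors with a clear message.
#   * tiny_cnn - a frozen seeded random-weight pyramid designed for texture
#     work on CPU. Each of the four stride-2 levels carries two channel
#     groups: rectified responses of random He-scaled filters (first-moment,
#     brightness-sensitive, lightly pooled so lesion contrast stays sharp)
#     and rectified responses of the same filters made zero-mean
#     (brightness-invariant texture energy, pooled over wide windows so a
#     token summarizes local texture statistics rather than exact pattern
#     positions). Wide-support statistics are what make the four corneal
#     layer textures comparably predictable from spatial context, which the
#     neighbor-masked reconstruction relies on.
#
# Feature maps are carried as token-major matrices (T x C) in row-major
# raster order of the spatial grid, the same serialization the transformer
# uses, with the grid dims kept in attributes.

TINY_CNN_STREAM_CHANNELS <- c(8L, 16L, 32L, 48L)
TINY_CNN_CHANNELS <- 2L * TINY_CNN_STREAM_CHANNELS
# per-level box-pooling widths (in level-grid cells) for the two streams
TINY_CNN_POOL_RAW <- c(9L, 5L, 3L, 1L)
TINY_CNN_POOL_ENERGY <- c(15L, 9L, 5L, 3L)

#' Backbone configuration
#'
#' @param name `"tiny_cnn"` or `"efficientnet_b3_pretrained"`.
#' @param frozen must be `TRUE`; backbone weights are never updated.
#' @param seed seed for the fixed random weights of `tiny_cnn`.
#' @return A `backbone_config` object with the per-level strides.
#' @export
backbone_config <- function(name = "tiny_cnn", frozen = TRUE, seed = 42L) {
  check_flag(name %in% c("tiny_cnn", "efficientnet_b3_pretrained"),
             "backbone name must be 'tiny_cnn' or 'efficientnet_b3_pretrained'")
  check_flag(isTRUE(frozen), "the backbone is always frozen")
  strides <- if (name == "tiny_cnn") c(2L, 4L, 8L, 16L) else c(4L, 8L, 16L, 32L)
  structure(list(name = name, frozen = TRUE, seed = as.integer(seed),
                 strides = strides),
            class = "backbone_config")
}

.backbone_cache <- new.env(parent = emptyenv())

# Fixed seeded He-scaled weights for the tiny backbone (memoized per seed).
# The energy stream uses the same filters with the mean removed per output
# channel, so it has no DC response.
tiny_cnn_weights <- function(seed) {
  key <- paste0("tiny_cnn_", seed)
  if (!is.null(.backbone_cache[[key]])) return(.backbone_cache[[key]])
  chans <- c(3L, TINY_CNN_STREAM_CHANNELS)
  w <- with_seed(derive_seed(seed, 101L), {
    lapply(seq_len(4L), function(l) {
      cin <- chans[l]; cout <- chans[l + 1]
      W <- matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                  9 * cin, cout)
      list(W = W, b = stats::rnorm(cout, 0, 0.05),
           Wz = sweep(W, 2, colMeans(W)))
    })
  })
  .backbone_cache[[key]] <- w
  w
}

# token-major (row-major raster) matrix <-> H x W x C array
tokmat_to_array <- function(m, h, w) {
  aperm(array(m, dim = c(w, h, ncol(m))), c(2, 1, 3))
}
array_to_tokmat <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(2, 1, 3)), d[1] * d[2], d[3])
}

# 3x3 conv, stride s, replicate padding 1, on H x W x C input; returns
# token-major matrix of the (H/s) x (W/s) output grid. Replicate (edge)
# padding avoids the artificial dark frame a zero pad would imprint on the
# border features.
conv3x3 <- function(x, W, b, stride) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  ho <- (h + 2 - 3) %/% stride + 1L
  wo <- (w + 2 - 3) %/% stride + 1L
  xp <- array(0, dim = c(h + 2, w + 2, cin))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  xp[1, 2:(w + 1), ] <- x[1, , ]
  xp[h + 2, 2:(w + 1), ] <- x[h, , ]
  xp[, 1, ] <- xp[, 2, ]
  xp[, w + 2, ] <- xp[, w + 1, ]
  cols <- vector("list", 9L)
  k <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1L
    rows <- seq(1 + dy, by = stride, length.out = ho)
    cls <- seq(1 + dx, by = stride, length.out = wo)
    cols[[k]] <- array_to_tokmat(xp[rows, cls, , drop = FALSE])
  }
  y <- do.call(cbind, cols) %*% W
  y <- sweep(y, 2, b, "+")
  attr(y, "grid") <- c(as.integer(ho), as.integer(wo))
  y
}

# Separable box filter with edge-renormalized windows (H x W x C array).
box_pool <- function(a, k) {
  if (k <= 1) return(a)
  h <- dim(a)[1]; w <- dim(a)[2]
  r <- (k - 1) / 2
  lo_h <- pmax(0, seq_len(h) - r - 1); hi_h <- pmin(h, seq_len(h) + r)
  lo_w <- pmax(0, seq_len(w) - r - 1); hi_w <- pmin(w, seq_len(w) + r)
  for (ch in seq_len(dim(a)[3])) {
    cs <- rbind(0, apply(a[, , ch], 2, cumsum))
    m <- (cs[hi_h + 1, , drop = FALSE] - cs[lo_h + 1, , drop = FALSE]) / (hi_h - lo_h)
    cs <- cbind(0, t(apply(m, 1, cumsum)))
    a[, , ch] <- sweep(cs[, hi_w + 1, drop = FALSE] - cs[, lo_w + 1, drop = FALSE],
                       2, hi_w - lo_w, "/")
  }
  a
}

#' Extract a frozen multi-scale feature pyramid
#'
#' @param image `H x W x 3` numeric array on the 0-255 scale (channels
#'   identical for grayscale input), or a list of such arrays.
#' @param cfg a [backbone_config()].
#' @return A `feature_pyramid`: list with `levels` (four token-major
#'   matrices with a `grid` attribute), `strides`, and `input_size`. For a
#'   list input, a list of pyramids.
#' @export
extract_pyramid <- function(image, cfg) {
  check_flag(inherits(cfg, "backbone_config"), "`cfg` must be a backbone_config")
  if (is.list(image) && !is.array(image)) {
    return(lapply(image, extract_pyramid, cfg = cfg))
  }
  if (cfg$name == "efficientnet_b3_pretrained") {
    stop_invalid(paste("pretrained EfficientNet-B3 weights are not bundled with this",
                       "package; use the 'tiny_cnn' backbone"),
                 class = "ivcmad_unavailable_backbone")
  }
  check_flag(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L,
             "`image` must be an H x W x 3 array")
  h <- dim(image)[1]; w <- dim(image)[2]
  ms <- max(cfg$strides)
  check_flag(h %% ms == 0L && w %% ms == 0L,
             sprintf("input size must be divisible by the maximum stride (%d)", ms))
  wts <- tiny_cnn_weights(cfg$seed)
  xr <- image / 255 - 0.5
  xe <- xr
  levels <- vector("list", 4L)
  for (l in seq_len(4L)) {
    yr <- conv3x3(xr, wts[[l]]$W, wts[[l]]$b, stride = 2L)
    g <- attr(yr, "grid")
    yr[] <- pmax(yr, 0)
    ar <- box_pool(tokmat_to_array(yr, g[1], g[2]), TINY_CNN_POOL_RAW[l])
    ye <- conv3x3(xe, wts[[l]]$Wz, wts[[l]]$b * 0, stride = 2L)
    ye[] <- abs(ye)
    ae <- box_pool(tokmat_to_array(ye, g[1], g[2]), TINY_CNN_POOL_ENERGY[l])
    m <- cbind(array_to_tokmat(ar), array_to_tokmat(ae))
    attr(m, "grid") <- g
    levels[[l]] <- m
    xr <- ar
    xe <- ae
  }
  structure(list(levels = levels, strides = cfg$strides, input_size = c(h, w)),
            class = "feature_pyramid")
}
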