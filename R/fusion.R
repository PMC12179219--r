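# Multi-Scale Feature Fusion Network (MFFN).
#
# Each pyramid level is linearly embedded (1x1 projection) to D/4 channels,
# resampled bilinearly onto the output-stride token grid, concatenated along
# channels to width D, and passed token-wise through a three-layer fully
# connected network. Bilinear resampling is realized as a precomputed linear
# operator (a T_out x T_in matrix), so its backward pass is the transpose.

#' Bilinear resampling operator between two grids
#'
#' Half-pixel-center bilinear interpolation from an `in_h x in_w` grid to an
#' `out_h x out_w` grid, as a dense matrix acting on row-major flattened
#' grids. Works for both down- and up-sampling.
#'
#' @param in_h,in_w,out_h,out_w grid dimensions.
#' @return Matrix of size `(out_h*out_w) x (in_h*in_w)`.
#' @keywords internal
bilinear_matrix <- function(in_h, in_w, out_h, out_w) {
  m <- matrix(0, out_h * out_w, in_h * in_w)
  sy <- clip((seq_len(out_h) - 0.5) * in_h / out_h - 0.5, 0, in_h - 1)
  sx <- clip((seq_len(out_w) - 0.5) * in_w / out_w - 0.5, 0, in_w - 1)
  y0 <- pmin(floor(sy), in_h - 2); wy <- sy - y0
  x0 <- pmin(floor(sx), in_w - 2); wx <- sx - x0
  if (in_h == 1) { y0 <- rep(0, out_h); wy <- rep(0, out_h) }
  if (in_w == 1) { x0 <- rep(0, out_w); wx <- rep(0, out_w) }
  for (r in seq_len(out_h)) {
    for (c in seq_len(out_w)) {
      t_out <- (r - 1) * out_w + c
      i0 <- y0[r] * in_w + x0[c] + 1
      m[t_out, i0] <- (1 - wy[r]) * (1 - wx[c])
      if (in_w > 1) m[t_out, i0 + 1] <- (1 - wy[r]) * wx[c]
      if (in_h > 1) m[t_out, i0 + in_w] <- wy[r] * (1 - wx[c])
      if (in_h > 1 && in_w > 1) m[t_out, i0 + in_w + 1] <- wy[r] * wx[c]
    }
  }
  m
}

# Xavier-uniform matrix
init_linear <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Initialize fusion parameters for given per-level channel counts.
init_fusion_params <- function(channels, d) {
  check_flag(d %% 4 == 0, "hidden dimension must be divisible by 4")
  p <- d %/% 4L
  theta <- list()
  for (l in seq_along(channels)) {
    theta[[sprintf("fus.emb%d.W", l)]] <- init_linear(channels[l], p)
    theta[[sprintf("fus.emb%d.b", l)]] <- numeric(p)
  }
  for (k in 1:3) {
    theta[[sprintf("fus.fcn%d.W", k)]] <- init_linear(d, d)
    theta[[sprintf("fus.fcn%d.b", k)]] <- numeric(d)
  }
  theta
}

# Forward pass of the fusion network for one pyramid.
# resize_mats: list of per-level bilinear operators onto the output grid.
fusion_forward <- function(theta, pyr, resize_mats, want_cache = FALSE) {
  nlev <- length(pyr$levels)
  embs <- vector("list", nlev)
  for (l in seq_len(nlev)) {
    e <- pyr$levels[[l]] %*% theta[[sprintf("fus.emb%d.W", l)]]
    e <- sweep(e, 2, theta[[sprintf("fus.emb%d.b", l)]], "+")
    embs[[l]] <- resize_mats[[l]] %*% e
  }
  x0 <- do.call(cbind, embs)
  z1 <- x0 %*% theta[["fus.fcn1.W"]]; z1 <- sweep(z1, 2, theta[["fus.fcn1.b"]], "+")
  a1 <- pmax(z1, 0)
  z2 <- a1 %*% theta[["fus.fcn2.W"]]; z2 <- sweep(z2, 2, theta[["fus.fcn2.b"]], "+")
  a2 <- pmax(z2, 0)
  z3 <- a2 %*% theta[["fus.fcn3.W"]]; z3 <- sweep(z3, 2, theta[["fus.fcn3.b"]], "+")
  # Fixed image-level standardization of the fused map. The four corneal
  # layer classes drive very different backbone activation magnitudes;
  # without this the L2 reconstruction error (and hence the anomaly score)
  # tracks layer brightness instead of structural deviation. The location
  # and scale are robust (median / MAD) so a lesion occupying a minority of
  # the image cannot drag the statistics and inflate the error of its
  # normal surroundings, and they are treated as constants in the backward
  # pass (standard stop-gradient on normalization statistics).
  mu <- stats::median(z3)
  inv <- 1 / (1.4826 * stats::median(abs(z3 - mu)) + 1e-8)
  out <- (z3 - mu) * inv
  cache <- if (want_cache) list(levels = pyr$levels, x0 = x0, z1 = z1, a1 = a1,
                                z2 = z2, a2 = a2,
                                ln = list(inv = inv))
           else NULL
  list(out = out, cache = cache)
}

fusion_backward <- function(theta, cache, resize_mats, dout, grads) {
  d <- ncol(dout)
  p <- d %/% 4L
  # backward through the fixed standardization (stats detached)
  dout <- dout * cache$ln$inv
  add_grad(grads, "fus.fcn3.W", crossprod(cache$a2, dout))
  add_grad(grads, "fus.fcn3.b", colSums(dout))
  da2 <- dout %*% t(theta[["fus.fcn3.W"]])
  dz2 <- da2 * (cache$z2 > 0)
  add_grad(grads, "fus.fcn2.W", crossprod(cache$a1, dz2))
  add_grad(grads, "fus.fcn2.b", colSums(dz2))
  da1 <- dz2 %*% t(theta[["fus.fcn2.W"]])
  dz1 <- da1 * (cache$z1 > 0)
  add_grad(grads, "fus.fcn1.W", crossprod(cache$x0, dz1))
  add_grad(grads, "fus.fcn1.b", colSums(dz1))
  dx0 <- dz1 %*% t(theta[["fus.fcn1.W"]])
  for (l in seq_along(cache$levels)) {
    dr <- dx0[, ((l - 1) * p + 1):(l * p), drop = FALSE]
    de <- crossprod(resize_mats[[l]], dr)
    add_grad(grads, sprintf("fus.emb%d.W", l), crossprod(cache$levels[[l]], de))
    add_grad(grads, sprintf("fus.emb%d.b", l), colSums(de))
  }
  invisible(NULL)
}

#' Embed and fuse a feature pyramid into the token grid
#'
#' Convenience wrapper running the fusion network with freshly initialized
#' (seeded) parameters unless `theta` is supplied; model training uses the
#' parameters held in the model object.
#'
#' @param pyr a `feature_pyramid` from [extract_pyramid()].
#' @param outstride output stride; must be one of the pyramid strides.
#' @param d hidden dimension (divisible by 4).
#' @param theta optional named parameter list (as held by an `ad_model`).
#' @param seed seed for parameter initialization when `theta` is `NULL`.
#' @return A `fused_feature_map`: `(H*W) x D` matrix in row-major token
#'   order with attributes `grid_h`, `grid_w`.
#' @export
embed_and_fuse <- function(pyr, outstride, d, theta = NULL, seed = 1L) {
  check_flag(inherits(pyr, "feature_pyramid"), "`pyr` must be a feature_pyramid")
  check_flag(outstride %in% pyr$strides, "`outstride` must be one of the pyramid strides")
  check_flag(d %% 4 == 0, "hidden dimension must be divisible by 4")
  gh <- pyr$input_size[1] %/% outstride
  gw <- pyr$input_size[2] %/% outstride
  mats <- lapply(pyr$levels, function(lv) {
    g <- attr(lv, "grid")
    bilinear_matrix(g[1], g[2], gh, gw)
  })
  if (is.null(theta)) {
    channels <- vapply(pyr$levels, ncol, integer(1))
    theta <- with_seed(derive_seed(seed, 7001L), init_fusion_params(channels, d))
  }
  out <- fusion_forward(theta, pyr, mats)$out
  fused_feature_map(out, gh, gw)
}

fused_feature_map <- function(m, gh, gw) {
  structure(m, grid_h = gh, grid_w = gw, class = c("fused_feature_map", class(m)))
}
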