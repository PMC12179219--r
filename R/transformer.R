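# Reconstruction transformer: Neighbor Masked Encoders (NME) and Layer-wise
# Query Decoders (LQD), with full analytic backpropagation in plain matrix
# code.
#
# Conventions (fixed for reproducibility):
#   * tokens are serialized in row-major raster order of the H x W grid;
#   * blocks are pre-norm with residual connections;
#   * one learnable position table is shared by all attention modules and is
#     added to the inputs of the query and key projections (not values);
#   * encoder self-attention is neighbor-masked; decoder attentions are not.

new_grads <- function() new.env(parent = emptyenv())

add_grad <- function(grads, key, val) {
  cur <- grads[[key]]
  grads[[key]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

#' Build the neighbor-prohibition attention mask
#'
#' `prohibition[q, k]` is `TRUE` when key `k` lies inside the `m_h x m_w`
#' window centered on query `q` in the `H x W` token grid (row-major order);
#' those pairs receive exactly zero attention weight. Windows are clipped at
#' the grid border (no wraparound). Self-attention of a token to itself is
#' always prohibited since the window is at least 1 x 1.
#'
#' @param h,w token-grid dimensions.
#' @param m_h,m_w odd window sizes (>= 1).
#' @return A `neighbor_mask`: list with the logical `prohibition` matrix of
#'   size `(h*w) x (h*w)`, `grid = c(h, w)`, `window = c(m_h, m_w)`.
#' @export
build_neighbor_mask <- function(h, w, m_h = 9L, m_w = 9L) {
  h <- check_count(h, 1L); w <- check_count(w, 1L)
  m_h <- check_count(m_h, 1L); m_w <- check_count(m_w, 1L)
  check_flag(m_h %% 2L == 1L && m_w %% 2L == 1L, "mask window sizes must be odd")
  rr <- rep(seq_len(h), each = w)
  cc <- rep(seq_len(w), times = h)
  proh <- (abs(outer(rr, rr, "-")) <= (m_h - 1L) %/% 2L) &
          (abs(outer(cc, cc, "-")) <= (m_w - 1L) %/% 2L)
  if (any(rowSums(proh) == h * w)) {
    stop_invalid(sprintf(
      "neighbor window [%d,%d] leaves some query on the %dx%d grid with no permitted key",
      m_h, m_w, h, w), class = "ivcmad_invalid_configuration")
  }
  structure(list(prohibition = proh, grid = c(h, w), window = c(m_h, m_w)),
            class = "neighbor_mask")
}

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# ---- layer normalization -------------------------------------------------

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, g, "*")
  y <- sweep(y, 2, b, "+")
  list(out = y, cache = list(xhat = xhat, inv = inv, g = g))
}

ln_backward <- function(cache, dy, grads, gkey, bkey) {
  xhat <- cache$xhat
  add_grad(grads, gkey, colSums(dy * xhat))
  add_grad(grads, bkey, colSums(dy))
  dxhat <- sweep(dy, 2, cache$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  (dxhat - m1 - xhat * m2) * cache$inv
}

# ---- dropout -------------------------------------------------------------

drop_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  keep <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(out = x * keep, mask = keep)
}

drop_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- multi-head attention ------------------------------------------------

# xq: query-side input (T_q x D); xkv: key/value-side input (T_k x D).
# pos is added to the projection inputs of queries and keys only.
mha_forward <- function(theta, prefix, xq, xkv, pos_q, pos_k, n_heads,
                       prohibition = NULL) {
  d <- ncol(xq)
  dh <- d %/% n_heads
  qin <- xq + pos_q
  kin <- xkv + pos_k
  q <- sweep(qin %*% theta[[paste0(prefix, ".Wq")]], 2, theta[[paste0(prefix, ".bq")]], "+")
  k <- sweep(kin %*% theta[[paste0(prefix, ".Wk")]], 2, theta[[paste0(prefix, ".bk")]], "+")
  v <- sweep(xkv %*% theta[[paste0(prefix, ".Wv")]], 2, theta[[paste0(prefix, ".bv")]], "+")
  o <- matrix(0, nrow(xq), d)
  aa <- vector("list", n_heads)
  for (hh in seq_len(n_heads)) {
    idx <- ((hh - 1) * dh + 1):(hh * dh)
    s <- tcrossprod(q[, idx, drop = FALSE], k[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(prohibition)) s[prohibition] <- -Inf
    a <- softmax_rows(s)
    aa[[hh]] <- a
    o[, idx] <- a %*% v[, idx, drop = FALSE]
  }
  out <- sweep(o %*% theta[[paste0(prefix, ".Wo")]], 2, theta[[paste0(prefix, ".bo")]], "+")
  list(out = out,
       cache = list(qin = qin, kin = kin, xkv = xkv, q = q, k = k, v = v,
                    a = aa, o = o, n_heads = n_heads, dh = dh))
}

# Returns list(dxq, dxkv, dpos_q, dpos_k)
mha_backward <- function(theta, prefix, cache, dout, grads) {
  o <- cache$o
  add_grad(grads, paste0(prefix, ".Wo"), crossprod(o, dout))
  add_grad(grads, paste0(prefix, ".bo"), colSums(dout))
  do <- dout %*% t(theta[[paste0(prefix, ".Wo")]])
  dh <- cache$dh
  dq <- matrix(0, nrow(cache$q), ncol(cache$q))
  dk <- matrix(0, nrow(cache$k), ncol(cache$k))
  dv <- matrix(0, nrow(cache$v), ncol(cache$v))
  for (hh in seq_len(cache$n_heads)) {
    idx <- ((hh - 1) * dh + 1):(hh * dh)
    a <- cache$a[[hh]]
    doh <- do[, idx, drop = FALSE]
    da <- tcrossprod(doh, cache$v[, idx, drop = FALSE])
    dv[, idx] <- crossprod(a, doh)
    ds <- a * (da - rowSums(a * da))
    dq[, idx] <- ds %*% cache$k[, idx, drop = FALSE] / sqrt(dh)
    dk[, idx] <- crossprod(ds, cache$q[, idx, drop = FALSE]) / sqrt(dh)
  }
  add_grad(grads, paste0(prefix, ".Wq"), crossprod(cache$qin, dq))
  add_grad(grads, paste0(prefix, ".bq"), colSums(dq))
  add_grad(grads, paste0(prefix, ".Wk"), crossprod(cache$kin, dk))
  add_grad(grads, paste0(prefix, ".bk"), colSums(dk))
  add_grad(grads, paste0(prefix, ".Wv"), crossprod(cache$xkv, dv))
  add_grad(grads, paste0(prefix, ".bv"), colSums(dv))
  dqin <- dq %*% t(theta[[paste0(prefix, ".Wq")]])
  dkin <- dk %*% t(theta[[paste0(prefix, ".Wk")]])
  dxkv <- dkin + dv %*% t(theta[[paste0(prefix, ".Wv")]])
  list(dxq = dqin, dxkv = dxkv, dpos_q = dqin, dpos_k = dkin)
}

# ---- feed-forward network ------------------------------------------------

ffn_forward <- function(theta, prefix, x, dropout, training) {
  z1 <- sweep(x %*% theta[[paste0(prefix, ".W1")]], 2, theta[[paste0(prefix, ".b1")]], "+")
  a1 <- pmax(z1, 0)
  dp <- drop_forward(a1, dropout, training)
  y <- sweep(dp$out %*% theta[[paste0(prefix, ".W2")]], 2, theta[[paste0(prefix, ".b2")]], "+")
  list(out = y, cache = list(x = x, z1 = z1, h = dp$out, mask = dp$mask))
}

ffn_backward <- function(theta, prefix, cache, dy, grads) {
  add_grad(grads, paste0(prefix, ".W2"), crossprod(cache$h, dy))
  add_grad(grads, paste0(prefix, ".b2"), colSums(dy))
  dh <- dy %*% t(theta[[paste0(prefix, ".W2")]])
  dh <- drop_backward(dh, cache$mask)
  dz1 <- dh * (cache$z1 > 0)
  add_grad(grads, paste0(prefix, ".W1"), crossprod(cache$x, dz1))
  add_grad(grads, paste0(prefix, ".b1"), colSums(dz1))
  dz1 %*% t(theta[[paste0(prefix, ".W1")]])
}

# ---- parameter initialization -------------------------------------------

# Residual-branch output projections (attention Wo, FFN W2) start at zero,
# so the untrained network is the identity on its residual stream and the
# reconstruction starts from the standardized-map origin instead of random
# noise; with few optimization steps this matters.
init_attention <- function(theta, prefix, d) {
  for (nm in c("Wq", "Wk", "Wv")) theta[[paste0(prefix, ".", nm)]] <- init_linear(d, d)
  theta[[paste0(prefix, ".Wo")]] <- matrix(0, d, d)
  for (nm in c("bq", "bk", "bv", "bo")) theta[[paste0(prefix, ".", nm)]] <- numeric(d)
  theta
}

init_ln <- function(theta, prefix, d) {
  theta[[paste0(prefix, ".g")]] <- rep(1, d)
  theta[[paste0(prefix, ".b")]] <- numeric(d)
  theta
}

init_ffn <- function(theta, prefix, d, f) {
  theta[[paste0(prefix, ".W1")]] <- init_linear(d, f)
  theta[[paste0(prefix, ".b1")]] <- numeric(f)
  theta[[paste0(prefix, ".W2")]] <- matrix(0, f, d)
  theta[[paste0(prefix, ".b2")]] <- numeric(d)
  theta
}

init_transformer_params <- function(cfg, n_tokens) {
  d <- cfg$hidden_dim
  theta <- list()
  theta[["pos"]] <- matrix(stats::rnorm(n_tokens * d, 0, 0.02), n_tokens, d)
  for (i in seq_len(cfg$n_encoder_layers)) {
    p <- sprintf("enc%d", i)
    theta <- init_ln(theta, paste0(p, ".ln1"), d)
    theta <- init_attention(theta, paste0(p, ".att"), d)
    theta <- init_ln(theta, paste0(p, ".ln2"), d)
    theta <- init_ffn(theta, paste0(p, ".ffn"), d, cfg$ffn_dim)
  }
  theta <- init_ln(theta, "encN.ln", d)
  for (i in seq_len(cfg$n_decoder_layers)) {
    p <- sprintf("dec%d", i)
    theta[[paste0(p, ".q")]] <- matrix(stats::rnorm(n_tokens * d, 0, 0.02), n_tokens, d)
    theta <- init_ln(theta, paste0(p, ".lnq"), d)
    theta <- init_ln(theta, paste0(p, ".lnp"), d)
    theta <- init_attention(theta, paste0(p, ".att1"), d)
    theta <- init_ln(theta, paste0(p, ".ln1"), d)
    theta <- init_attention(theta, paste0(p, ".att2"), d)
    theta <- init_ln(theta, paste0(p, ".ln2"), d)
    theta <- init_ffn(theta, paste0(p, ".ffn"), d, cfg$ffn_dim)
  }
  theta
}

# ---- encoder -------------------------------------------------------------

#' Run the neighbor-masked encoder stack
#'
#' @param f_org fused feature map, `(H*W) x D` matrix in row-major order.
#' @param theta named parameter list.
#' @param cfg transformer configuration (`hidden_dim`, `n_heads`,
#'   `n_encoder_layers`, `ffn_dim`, `dropout`).
#' @param mask a [build_neighbor_mask()] result matching the token grid.
#' @param training enable dropout.
#' @param want_cache keep forward caches for backpropagation.
#' @return list with `out` (encoder embeddings, `(H*W) x D`) and `cache`.
#' @export
encode <- function(f_org, theta, cfg, mask, training = FALSE, want_cache = FALSE) {
  check_flag(nrow(mask$prohibition) == nrow(f_org),
             "neighbor mask grid does not match the token grid")
  check_flag(ncol(f_org) == cfg$hidden_dim, "feature width does not match hidden_dim")
  pos <- theta[["pos"]]
  x <- f_org
  caches <- vector("list", cfg$n_encoder_layers)
  for (i in seq_len(cfg$n_encoder_layers)) {
    p <- sprintf("enc%d", i)
    l1 <- ln_forward(x, theta[[paste0(p, ".ln1.g")]], theta[[paste0(p, ".ln1.b")]])
    at <- mha_forward(theta, paste0(p, ".att"), l1$out, l1$out, pos, pos,
                      cfg$n_heads, mask$prohibition)
    d1 <- drop_forward(at$out, cfg$dropout, training)
    x1 <- x + d1$out
    l2 <- ln_forward(x1, theta[[paste0(p, ".ln2.g")]], theta[[paste0(p, ".ln2.b")]])
    ff <- ffn_forward(theta, paste0(p, ".ffn"), l2$out, cfg$dropout, training)
    d2 <- drop_forward(ff$out, cfg$dropout, training)
    xo <- x1 + d2$out
    caches[[i]] <- list(l1 = l1, at = at, d1 = d1$mask, l2 = l2, ff = ff, d2 = d2$mask)
    x <- xo
  }
  lf <- ln_forward(x, theta[["encN.ln.g"]], theta[["encN.ln.b"]])
  list(out = lf$out,
       cache = if (want_cache) list(layers = caches, lf = lf) else NULL)
}

encode_backward <- function(theta, cfg, cache, dout, grads) {
  dx <- ln_backward(cache$lf$cache, dout, grads, "encN.ln.g", "encN.ln.b")
  for (i in rev(seq_len(cfg$n_encoder_layers))) {
    p <- sprintf("enc%d", i)
    cc <- cache$layers[[i]]
    dff <- drop_backward(dx, cc$d2)
    dn2 <- ffn_backward(theta, paste0(p, ".ffn"), cc$ff$cache, dff, grads)
    dx1 <- dx + ln_backward(cc$l2$cache, dn2, grads,
                            paste0(p, ".ln2.g"), paste0(p, ".ln2.b"))
    dat <- drop_backward(dx1, cc$d1)
    mb <- mha_backward(theta, paste0(p, ".att"), cc$at$cache, dat, grads)
    add_grad(grads, "pos", mb$dpos_q + mb$dpos_k)
    dn1 <- mb$dxq + mb$dxkv
    dx <- dx1 + ln_backward(cc$l1$cache, dn1, grads,
                            paste0(p, ".ln1.g"), paste0(p, ".ln1.b"))
  }
  dx
}

# ---- decoder -------------------------------------------------------------

#' Run the layer-wise query decoder stack
#'
#' Each decoder layer owns a learnable query embedding. Its first attention
#' uses that embedding as the query side against the previous layer's output
#' (the first layer attends to its own query embedding, i.e. self-fusion);
#' the second attention cross-attends to the encoder embeddings; an FFN
#' closes the block. The last layer's output is the reconstructed feature
#' map `f_rec`.
#'
#' The cross-attention to the encoder embeddings is neighbor-masked with the
#' same window as the encoder: the residual stream of the encoder carries
#' each token's original feature, so an unmasked cross-attention would let
#' the decoder copy every token's ground truth verbatim and reconstruction
#' error would stop carrying anomaly signal. The first attention (query
#' embedding against the previous layer's output) is unmasked: the previous
#' output is itself a context-only prediction, not ground truth.
#'
#' @param enc encoder embeddings, `(H*W) x D`.
#' @inheritParams encode
#' @return list with `out` (`f_rec`) and `cache`.
#' @export
decode <- function(enc, theta, cfg, mask = NULL, training = FALSE, want_cache = FALSE) {
  check_flag(ncol(enc) == cfg$hidden_dim, "feature width does not match hidden_dim")
  pos <- theta[["pos"]]
  caches <- vector("list", cfg$n_decoder_layers)
  p_out <- NULL
  for (i in seq_len(cfg$n_decoder_layers)) {
    p <- sprintf("dec%d", i)
    qi <- theta[[paste0(p, ".q")]]
    prev <- if (i == 1) qi else p_out
    lq <- ln_forward(qi, theta[[paste0(p, ".lnq.g")]], theta[[paste0(p, ".lnq.b")]])
    lp <- ln_forward(prev, theta[[paste0(p, ".lnp.g")]], theta[[paste0(p, ".lnp.b")]])
    a1 <- mha_forward(theta, paste0(p, ".att1"), lq$out, lp$out, pos, pos, cfg$n_heads)
    da1 <- drop_forward(a1$out, cfg$dropout, training)
    x1 <- prev + da1$out
    l1 <- ln_forward(x1, theta[[paste0(p, ".ln1.g")]], theta[[paste0(p, ".ln1.b")]])
    a2 <- mha_forward(theta, paste0(p, ".att2"), l1$out, enc, pos, pos, cfg$n_heads,
                      if (is.null(mask)) NULL else mask$prohibition)
    da2 <- drop_forward(a2$out, cfg$dropout, training)
    x2 <- x1 + da2$out
    l2 <- ln_forward(x2, theta[[paste0(p, ".ln2.g")]], theta[[paste0(p, ".ln2.b")]])
    ff <- ffn_forward(theta, paste0(p, ".ffn"), l2$out, cfg$dropout, training)
    df <- drop_forward(ff$out, cfg$dropout, training)
    p_new <- x2 + df$out
    caches[[i]] <- list(lq = lq, lp = lp, a1 = a1, d1 = da1$mask, l1 = l1,
                        a2 = a2, d2 = da2$mask, l2 = l2, ff = ff, d3 = df$mask)
    p_out <- p_new
  }
  list(out = p_out, cache = if (want_cache) list(layers = caches) else NULL)
}

# Returns d_enc (gradient wrt the encoder embeddings).
decode_backward <- function(theta, cfg, cache, dout, grads) {
  denc <- 0
  dp <- dout
  for (i in rev(seq_len(cfg$n_decoder_layers))) {
    p <- sprintf("dec%d", i)
    cc <- cache$layers[[i]]
    dff <- drop_backward(dp, cc$d3)
    dn2 <- ffn_backward(theta, paste0(p, ".ffn"), cc$ff$cache, dff, grads)
    dx2 <- dp + ln_backward(cc$l2$cache, dn2, grads,
                            paste0(p, ".ln2.g"), paste0(p, ".ln2.b"))
    da2 <- drop_backward(dx2, cc$d2)
    mb2 <- mha_backward(theta, paste0(p, ".att2"), cc$a2$cache, da2, grads)
    add_grad(grads, "pos", mb2$dpos_q + mb2$dpos_k)
    denc <- denc + mb2$dxkv
    dx1 <- dx2 + ln_backward(cc$l1$cache, mb2$dxq, grads,
                             paste0(p, ".ln1.g"), paste0(p, ".ln1.b"))
    da1 <- drop_backward(dx1, cc$d1)
    mb1 <- mha_backward(theta, paste0(p, ".att1"), cc$a1$cache, da1, grads)
    add_grad(grads, "pos", mb1$dpos_q + mb1$dpos_k)
    dq <- ln_backward(cc$lq$cache, mb1$dxq, grads,
                      paste0(p, ".lnq.g"), paste0(p, ".lnq.b"))
    dprev <- dx1 + ln_backward(cc$lp$cache, mb1$dxkv, grads,
                               paste0(p, ".lnp.g"), paste0(p, ".lnp.b"))
    if (i == 1) {
      add_grad(grads, paste0(p, ".q"), dq + dprev)
      dp <- NULL
    } else {
      add_grad(grads, paste0(p, ".q"), dq)
      dp <- dprev
    }
  }
  denc
}
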