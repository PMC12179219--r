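test_that("neighbor mask matches the window definition and its degenerate cases", {
  # window of one: each token prohibits only itself
  nm <- build_neighbor_mask(2, 2, 1, 1)
  expect_identical(nm$prohibition, diag(4) == 1)

  # corner and interior counts on a 4x4 grid with a 3x3 window
  nm4 <- build_neighbor_mask(4, 4, 3, 3)
  corner <- which(nm4$prohibition[1, ])
  expect_setequal(corner, c(1, 2, 5, 6))          # (0,0),(0,1),(1,0),(1,1) row-major
  centre <- (2 - 1) * 4 + 2                       # grid position (2,2)
  expect_equal(sum(nm4$prohibition[centre, ]), 9)

  # symmetry and diagonal, across several geometries
  for (g in list(c(3, 5, 1, 3), c(6, 4, 5, 3))) {
    m <- build_neighbor_mask(g[1], g[2], g[3], g[4])$prohibition
    expect_identical(m, t(m))
    expect_true(all(diag(m)))
  }

  # a window covering the whole grid leaves no permitted key
  expect_error(build_neighbor_mask(3, 3, 9, 9), class = "ivcmad_invalid_configuration")
  expect_error(build_neighbor_mask(4, 4, 2, 3), "odd")
})

test_that("masked attention rows are proper distributions over permitted keys", {
  cfg <- micro_config()
  model <- ad_model(cfg)
  x <- random_fused_map(16, 8, seed = 2)
  at <- ivcmad:::mha_forward(model$theta, "enc1.att", x, x,
                             model$theta$pos, model$theta$pos,
                             cfg$n_heads, model$mask$prohibition)
  for (a in at$cache$a) {
    expect_equal(rowSums(a), rep(1, 16))
    expect_true(all(a[model$mask$prohibition] == 0))
  }
})

test_that("prohibited keys contribute nothing to a query's attention output", {
  cfg <- micro_config()
  model <- ad_model(cfg)
  set.seed(30)
  model$theta[["enc1.att.Wo"]][] <- rnorm(64, 0, 0.3)  # active output projection
  x <- random_fused_map(16, 8, seed = 3)
  base <- ivcmad:::mha_forward(model$theta, "enc1.att", x, x,
                               model$theta$pos, model$theta$pos,
                               cfg$n_heads, model$mask$prohibition)$out
  k <- 6L                       # perturb one token's content arbitrarily
  x2 <- x
  x2[k, ] <- x2[k, ] + 100
  pert <- ivcmad:::mha_forward(model$theta, "enc1.att", x, x2,
                               model$theta$pos, model$theta$pos,
                               cfg$n_heads, model$mask$prohibition)$out
  blocked <- which(model$mask$prohibition[, k])
  expect_identical(base[blocked, ], pert[blocked, ])     # bitwise unchanged
  open <- which(!model$mask$prohibition[, k])
  expect_false(isTRUE(all.equal(base[open, ], pert[open, ])))
})

test_that("encoder and decoder preserve shape and are deterministic at dropout 0", {
  cfg <- micro_config()
  model <- ad_model(cfg)
  f <- random_fused_map(16, 8, seed = 4)
  e1 <- encode(f, model$theta, cfg, model$mask)
  e2 <- encode(f, model$theta, cfg, model$mask)
  expect_identical(e1$out, e2$out)
  expect_equal(dim(e1$out), dim(f))
  d1 <- decode(e1$out, model$theta, cfg, mask = model$mask)
  expect_identical(d1$out, decode(e1$out, model$theta, cfg, mask = model$mask)$out)
  expect_equal(dim(d1$out), dim(f))
  expect_error(encode(random_fused_map(9, 8), model$theta, cfg, model$mask), "grid")
})

test_that("dropout during training perturbs activations but not inference", {
  cfg <- ad_config("tiny", input_size = 32L, outstride = 8L, hidden_dim = 8L,
                   n_heads = 2L, n_encoder_layers = 1L, n_decoder_layers = 1L,
                   ffn_dim = 12L, neighbor_mask = c(3L, 3L), dropout = 0.5)
  model <- ad_model(cfg)
  set.seed(31)
  for (nm in grep("\\.(Wo|W2)$", names(model$theta), value = TRUE)) {
    model$theta[[nm]][] <- rnorm(length(model$theta[[nm]]), 0, 0.3)
  }
  f <- random_fused_map(16, 8, seed = 5)
  set.seed(1)
  tr1 <- encode(f, model$theta, cfg, model$mask, training = TRUE)$out
  set.seed(2)
  tr2 <- encode(f, model$theta, cfg, model$mask, training = TRUE)$out
  expect_false(identical(tr1, tr2))
  expect_identical(encode(f, model$theta, cfg, model$mask)$out,
                   encode(f, model$theta, cfg, model$mask)$out)
})

test_that("decoding responds to encoder perturbations (non-degenerate cross-attention)", {
  cfg <- micro_config()
  model <- ad_model(cfg)
  # exercise a trained-like state: nudge the zero-initialized output
  # projections so residual branches are active
  set.seed(7)
  for (nm in grep("\\.(Wo|W2)$", names(model$theta), value = TRUE)) {
    model$theta[[nm]][] <- rnorm(length(model$theta[[nm]]), 0, 0.2)
  }
  f <- random_fused_map(16, 8, seed = 6)
  enc <- encode(f, model$theta, cfg, model$mask)$out
  base <- decode(enc, model$theta, cfg, mask = model$mask)$out
  eps <- 1e-4
  enc2 <- enc
  enc2[3, 5] <- enc2[3, 5] + eps
  pert <- decode(enc2, model$theta, cfg, mask = model$mask)$out
  sens <- sum(abs(pert - base)) / eps
  expect_gt(sens, 0)
})

test_that("reconstruction keeps shape and an untrained model has positive error", {
  cfg <- micro_config()
  model <- ad_model(cfg)
  img <- gen_layer_texture("stroma", 32, 9)
  fw <- ivcmad:::model_forward(model, ivcmad:::model_pyramid(model, img))
  expect_equal(dim(fw$f_rec), dim(fw$f_org))
  expect_gt(feature_mse_loss(fw$f_org, fw$f_rec), 0)
  f_rec2 <- reconstruct(fw$f_org, model)
  expect_equal(unclass(f_rec2), unclass(fw$f_rec), ignore_attr = TRUE)
})

test_that("analytic transformer gradients match finite differences", {
  cfg <- micro_config()
  model <- ad_model(cfg)
  # activate the residual branches so every parameter has gradient flow
  set.seed(11)
  for (nm in grep("\\.(Wo|W2)$", names(model$theta), value = TRUE)) {
    model$theta[[nm]][] <- rnorm(length(model$theta[[nm]]), 0, 0.2)
  }
  pyr <- ivcmad:::model_pyramid(model, gen_layer_texture("epithelium", 32, 5))
  loss_at <- function(m) {
    fw <- ivcmad:::model_forward(m, pyr)
    feature_mse_loss(fw$f_org, fw$f_rec)
  }
  fw <- ivcmad:::model_forward(model, pyr, want_cache = TRUE)
  grads <- ivcmad:::new_grads()
  ivcmad:::model_backward(model, fw, grads)
  eps <- 1e-5
  set.seed(12)
  keys <- grep("^fus", names(model$theta), invert = TRUE, value = TRUE)
  for (key in sample(keys, 12)) {
    g <- grads[[key]]
    skip_entry <- is.null(g)
    expect_false(skip_entry, info = key)
    i <- sample(length(model$theta[[key]]), 1)
    mp <- model; mp$theta[[key]][i] <- mp$theta[[key]][i] + eps
    mm <- model; mm$theta[[key]][i] <- mm$theta[[key]][i] - eps
    num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4,
                 info = sprintf("%s[%d]", key, i))
  }
})

test_that("the parameter count follows the closed-form expression", {
  count_for <- function(cfg, channels) {
    d <- cfg$hidden_dim; f <- cfg$ffn_dim
    tt <- (cfg$input_size / cfg$outstride)^2
    ln <- 2 * d
    attn <- 4 * d^2 + 4 * d
    ffn <- d * f + f + f * d + d
    fusion <- sum(channels * (d / 4) + d / 4) + 3 * (d^2 + d)
    enc <- cfg$n_encoder_layers * (2 * ln + attn + ffn) + ln
    dec <- cfg$n_decoder_layers * (tt * d + 4 * ln + 2 * attn + ffn)
    fusion + tt * d + enc + dec
  }
  cfg <- ad_config("tiny")
  expect_equal(n_parameters(ad_model(cfg)), count_for(cfg, c(16, 32, 64, 96)))
  cfg2 <- micro_config()
  expect_equal(n_parameters(ad_model(cfg2)), count_for(cfg2, c(16, 32, 64, 96)))
})
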