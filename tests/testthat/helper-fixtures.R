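# Shared fixtures. Everything is generated in code under fixed seeds.

# A micro model configuration small enough for finite-difference checks.
micro_config <- function() {
  ad_config("tiny", input_size = 32L, outstride = 8L, hidden_dim = 8L,
            n_heads = 2L, n_encoder_layers = 1L, n_decoder_layers = 2L,
            ffn_dim = 12L, neighbor_mask = c(3L, 3L))
}

random_fused_map <- function(t_tokens = 16, d = 8, seed = 1) {
  set.seed(seed)
  matrix(rnorm(t_tokens * d), t_tokens, d)
}

# Brute-force neighbor-window membership oracle.
brute_force_mask <- function(h, w, m_h, m_w) {
  tt <- h * w
  proh <- matrix(FALSE, tt, tt)
  for (q in seq_len(tt)) {
    qr <- (q - 1) %/% w + 1; qc <- (q - 1) %% w + 1
    for (k in seq_len(tt)) {
      kr <- (k - 1) %/% w + 1; kc <- (k - 1) %% w + 1
      proh[q, k] <- abs(qr - kr) <= (m_h - 1) / 2 && abs(qc - kc) <= (m_w - 1) / 2
    }
  }
  proh
}

# Rank-based AUC oracle: (wins + 0.5 ties) / (n_pos * n_neg).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# The end-to-end synthetic benchmark is expensive (a few minutes), so the
# trained model and its test scores are computed once and shared by every
# test that needs them.
.e2e_cache <- new.env(parent = emptyenv())

get_e2e <- function() {
  if (!is.null(.e2e_cache$res)) return(.e2e_cache$res)
  train_co <- build_synthetic_cohort(n_eyes = 50, images_per_eye = 4,
                                     anomalous_eye_fraction = 0, size = 64, seed = 101)
  test_co <- build_synthetic_cohort(n_eyes = 50, images_per_eye = 4,
                                    anomalous_eye_fraction = 0.5, size = 64, seed = 202)
  model <- ad_model(ad_config("tiny"))
  model <- train_model(model, train_co$images)
  model <- calibrate_score_scale(model, train_co$images)
  scores <- score_images(model, test_co$images)
  .e2e_cache$res <- list(model = model, train = train_co, test = test_co,
                         scores = scores)
  .e2e_cache$res
}
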