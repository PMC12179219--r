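# Normal-only training with the feature-MSE objective, AdamW optimization,
# and calibration of the raw 0-255 anomaly-score scale.

#' Feature-space mean squared error
#'
#' `Loss = (1 / (H*W)) * || f_org - f_rec ||_2^2`, i.e. the sum of squared
#' entrywise differences divided by the number of grid positions (not by the
#' hidden dimension).
#'
#' @param f_org,f_rec `(H*W) x D` matrices of identical shape.
#' @return Non-negative scalar; zero iff the maps are identical.
#' @export
feature_mse_loss <- function(f_org, f_rec) {
  check_flag(all(dim(f_org) == dim(f_rec)), "f_org and f_rec must have identical shape")
  sum((unclass(f_org) - unclass(f_rec))^2) / nrow(f_org)
}

# One AdamW step over all trainable tensors (decoupled weight decay; layer
# normalization gains/offsets and biases are not decayed, the usual
# convention).
adamw_step <- function(theta, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (key in names(theta)) {
    g <- grads[[key]]
    if (is.null(g)) next
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- g * 0
      state$v[[key]] <- g * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^t)
    vhat <- state$v[[key]] / (1 - beta2^t)
    decay <- if (grepl("\\.(b|bq|bk|bv|bo|b1|b2|g)$", key)) 0 else wd
    theta[[key]] <- theta[[key]] - lr * (mhat / (sqrt(vhat) + eps) + decay * theta[[key]])
  }
  theta
}

#' Train the reconstruction model on normal images
#'
#' The backbone stays frozen; only the fusion network and the transformer are
#' updated. Training hard-fails if any image is labeled anomalous - anomalous
#' records are never silently filtered out.
#'
#' @param model an [ad_model()].
#' @param images list of [ivcm_image()] objects, all labeled `"normal"`.
#' @param epochs number of epochs (0 returns the initialized model with an
#'   empty loss log).
#' @param batch_size minibatch size.
#' @param lr,weight_decay AdamW settings; default from the model config.
#' @param seed seed governing epoch shuffles and dropout.
#' @param verbose print per-epoch mean loss.
#' @return The trained `ad_model`, with `loss_log` (data.frame: epoch,
#'   mean_loss) attached.
#' @export
train_model <- function(model, images,
                        epochs = model$config$epochs,
                        batch_size = model$config$batch_size,
                        lr = model$config$learning_rate,
                        weight_decay = model$config$weight_decay,
                        seed = model$config$seed,
                        verbose = FALSE) {
  check_flag(inherits(model, "ad_model"), "`model` must be an ad_model")
  check_flag(length(images) >= 1, "need at least one training image")
  labels <- vapply(images, function(im) im$label, character(1))
  if (any(labels != "normal")) {
    stop_invalid(sprintf("training set contains %d anomalous image(s); only normal images may be used",
                         sum(labels != "normal")),
                 class = "ivcmad_train_purity_error")
  }
  epochs <- check_count(epochs, 0L)
  batch_size <- check_count(batch_size, 1L)

  pyrs <- lapply(images, function(im) model_pyramid(model, im))
  n <- length(pyrs)
  state <- new.env(parent = emptyenv())
  state$m <- list(); state$v <- list()
  t_step <- 0L
  log_rows <- vector("list", epochs)

  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 31L, ep), sample.int(n))
    losses <- c()
    for (b0 in seq(1, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      grads <- new_grads()
      bl <- 0
      for (j in seq_along(idx)) {
        fw <- with_seed(derive_seed(seed, 97L, ep, b0, j), {
          model_forward(model, pyrs[[idx[j]]], training = TRUE, want_cache = TRUE)
        })
        bl <- bl + feature_mse_loss(fw$f_org, fw$f_rec)
        model_backward(model, fw, grads)
      }
      # average the batch gradient
      for (key in ls(grads)) grads[[key]] <- grads[[key]] / length(idx)
      t_step <- t_step + 1L
      model$theta <- adamw_step(model$theta, grads, state, lr, weight_decay, t_step)
      losses <- c(losses, bl / length(idx))
    }
    log_rows[[ep]] <- data.frame(epoch = ep, mean_loss = mean(losses))
    if (verbose) message(sprintf("epoch %d  mean loss %.5f", ep, mean(losses)))
  }
  model$loss_log <- if (epochs > 0) do.call(rbind, log_rows) else
    data.frame(epoch = integer(0), mean_loss = numeric(0))
  model
}

#' Nearest-rank percentile
#'
#' Sorts `x` and returns the value at index `ceiling(p/100 * n)` (at least
#' 1). With all values equal it returns that value; with `p = 100` it
#' returns the maximum.
#'
#' @param x numeric vector.
#' @param p percentile in (0, 100].
#' @return The percentile value.
#' @export
nearest_rank_percentile <- function(x, p) {
  check_flag(length(x) >= 1, "empty vector")
  check_flag(p > 0 && p <= 100, "percentile must lie in (0, 100]")
  s <- sort(x)
  # small epsilon guards against floating error in p/100 * n landing a hair
  # above the exact integer rank
  s[max(1L, ceiling(p / 100 * length(s) - 1e-9))]
}

#' Calibrate the raw 0-255 anomaly-score scale
#'
#' Pools the per-token reconstruction errors of all training images and
#' stores their `scale_percentile`-th percentile as the error magnitude
#' mapped to 255. Scaled token errors are `clip(raw / scale_value, 0, 1) *
#' 255`, so the raw image score lives on a stable 0-255 scale across runs.
#'
#' @param model a trained [ad_model()].
#' @param images training images (list of [ivcm_image()]).
#' @param percentile percentile of pooled token errors mapped to 255.
#' @return The model with a `calibration` list (`scale_percentile`,
#'   `scale_value`) attached.
#' @export
calibrate_score_scale <- function(model, images,
                                  percentile = model$config$scale_percentile) {
  check_flag(inherits(model, "ad_model"), "`model` must be an ad_model")
  check_flag(length(images) >= 1, "empty training set")
  errs <- unlist(lapply(images, function(im) {
    fw <- model_forward(model, model_pyramid(model, im))
    sqrt(rowSums((unclass(fw$f_org) - unclass(fw$f_rec))^2))
  }))
  sv <- nearest_rank_percentile(errs, percentile)
  check_flag(sv > 0, "degenerate calibration: all token errors are zero")
  model$calibration <- list(scale_percentile = percentile, scale_value = sv)
  model
}

#' Save a model checkpoint
#'
#' A single archive holding a config echo, every learnable tensor keyed by
#' its dotted path, the score calibration, and a format-version string.
#'
#' @param model an `ad_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  check_flag(inherits(model, "ad_model"), "`model` must be an ad_model")
  saveRDS(list(format_version = model$format_version,
               config = unclass(model$config),
               theta = model$theta,
               calibration = model$calibration,
               loss_log = model$loss_log), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return An `ad_model` with the stored parameters and calibration.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  check_flag(identical(ck$format_version, "ivcmad-checkpoint-1"),
             sprintf("unsupported checkpoint format: %s", ck$format_version))
  cfg <- do.call(ad_config, c(list(profile = ck$config$profile),
                              ck$config[setdiff(names(ck$config), "profile")]))
  model <- ad_model(cfg)
  check_flag(identical(sort(names(model$theta)), sort(names(ck$theta))),
             "checkpoint parameters do not match the configured architecture")
  model$theta <- ck$theta
  model$calibration <- ck$calibration
  model$loss_log <- ck$loss_log
  model
}
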