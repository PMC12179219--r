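# Model assembly: configuration profiles, parameter initialization, and the
# fused forward/backward pass used by training and scoring.

#' Model configuration
#'
#' Two named profiles are provided. `"paper"` carries the full-scale
#' hyperparameters (384-pixel input, EfficientNet-B3 backbone, hidden
#' dimension 768, 8 heads, 7 encoder and 7 decoder layers, dropout 0.1,
#' relu, AdamW with learning rate 1e-4 and weight decay 1e-3, batch size 8,
#' neighbor mask \[9,9\], output stride 16). `"tiny"` is a CPU-scale profile
#' used throughout the test suite: 64-pixel input, frozen random `tiny_cnn`
#' backbone, hidden dimension 64, 4 heads, 2+2 layers, feed-forward width
#' 128, no dropout, neighbor mask \[3,3\], output stride 8, learning rate
#' 3e-3 (rescaled for the smaller model and short schedule), 5 epochs.
#'
#' @param profile `"tiny"` or `"paper"`.
#' @param ... named overrides of individual fields.
#' @return An `ad_config` list.
#' @export
ad_config <- function(profile = c("tiny", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(profile = "paper",
         input_size = 384L,
         backbone = "efficientnet_b3_pretrained",
         backbone_seed = 42L,
         outstride = 16L,
         hidden_dim = 768L,
         n_heads = 8L,
         n_encoder_layers = 7L,
         n_decoder_layers = 7L,
         ffn_dim = 3072L,
         dropout = 0.1,
         activation = "relu",
         neighbor_mask = c(9L, 9L),
         optimizer = "adamw",
         learning_rate = 1e-4,
         weight_decay = 1e-3,
         batch_size = 8L,
         epochs = 100L,
         scale_percentile = 99.9,
         seed = 1L)
  } else {
    list(profile = "tiny",
         input_size = 64L,
         backbone = "tiny_cnn",
         backbone_seed = 42L,
         outstride = 8L,
         hidden_dim = 64L,
         n_heads = 4L,
         n_encoder_layers = 2L,
         n_decoder_layers = 2L,
         ffn_dim = 128L,
         dropout = 0,
         activation = "relu",
         neighbor_mask = c(3L, 3L),
         optimizer = "adamw",
         learning_rate = 3e-3,
         weight_decay = 1e-3,
         batch_size = 8L,
         epochs = 5L,
         scale_percentile = 99.9,
         seed = 1L)
  }
  dots <- list(...)
  for (nm in names(dots)) {
    check_flag(nm %in% names(cfg), sprintf("unknown config field '%s'", nm))
    cfg[[nm]] <- dots[[nm]]
  }
  check_flag(cfg$hidden_dim %% cfg$n_heads == 0, "hidden_dim must be divisible by n_heads")
  check_flag(cfg$hidden_dim %% 4 == 0, "hidden_dim must be divisible by 4")
  check_flag(cfg$learning_rate > 0, "learning_rate must be positive")
  check_flag(cfg$batch_size >= 1, "batch_size must be >= 1")
  check_flag(all(cfg$neighbor_mask %% 2 == 1) && all(cfg$neighbor_mask >= 1),
             "neighbor mask dims must be odd and >= 1")
  structure(cfg, class = "ad_config")
}

#' Load a model configuration from a YAML file
#'
#' The file may set `profile:` and override any [ad_config()] field.
#'
#' @param path YAML file path.
#' @return An `ad_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "tiny"
  y$profile <- NULL
  do.call(ad_config, c(list(profile = profile), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an anomaly-detection model
#'
#' Initializes the trainable fusion and transformer parameters (seeded
#' width-scaled uniform weights), the frozen backbone, the neighbor mask and
#' the bilinear resampling operators for the configured geometry.
#'
#' @param config an [ad_config()].
#' @return An `ad_model` object.
#' @export
ad_model <- function(config = ad_config("tiny")) {
  check_flag(inherits(config, "ad_config"), "`config` must be an ad_config")
  bb <- backbone_config(config$backbone, seed = config$backbone_seed)
  check_flag(config$outstride %in% bb$strides,
             "outstride must be one of the backbone strides")
  check_flag(config$input_size %% max(bb$strides) == 0,
             "input size must be divisible by the largest backbone stride")
  gh <- config$input_size %/% config$outstride
  gw <- gh
  n_tokens <- gh * gw
  mask <- build_neighbor_mask(gh, gw, config$neighbor_mask[1], config$neighbor_mask[2])
  channels <- if (bb$name == "tiny_cnn") TINY_CNN_CHANNELS else c(32L, 48L, 136L, 384L)
  level_dims <- config$input_size %/% bb$strides
  resize_mats <- lapply(level_dims, function(s) bilinear_matrix(s, s, gh, gw))
  theta <- with_seed(derive_seed(config$seed, 8191L), {
    c(init_fusion_params(channels, config$hidden_dim),
      init_transformer_params(config, n_tokens))
  })
  structure(list(config = config, backbone = bb, grid = c(gh, gw),
                 mask = mask, resize_mats = resize_mats, theta = theta,
                 calibration = NULL, loss_log = NULL,
                 format_version = "ivcmad-checkpoint-1"),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("<ad_model profile=%s  grid %dx%d  D=%d  %d+%d layers  %s params%s>\n",
              x$config$profile, x$grid[1], x$grid[2], x$config$hidden_dim,
              x$config$n_encoder_layers, x$config$n_decoder_layers,
              format(n_parameters(x), big.mark = ","),
              if (is.null(x$calibration)) "" else "  calibrated"))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model an `ad_model`.
#' @return Integer count of all trainable scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$theta, length, numeric(1)))
}

# Full forward pass from a feature pyramid. Returns f_org, f_rec and (when
# requested) all caches needed for backpropagation.
model_forward <- function(model, pyr, training = FALSE, want_cache = FALSE) {
  fus <- fusion_forward(model$theta, pyr, model$resize_mats, want_cache = want_cache)
  f_org <- fus$out
  en <- encode(f_org, model$theta, model$config, model$mask,
               training = training, want_cache = want_cache)
  de <- decode(en$out, model$theta, model$config, mask = model$mask,
               training = training, want_cache = want_cache)
  list(f_org = fused_feature_map(f_org, model$grid[1], model$grid[2]),
       f_rec = fused_feature_map(de$out, model$grid[1], model$grid[2]),
       caches = if (want_cache) list(fus = fus$cache, en = en$cache, de = de$cache) else NULL)
}

# Backward pass for the feature-MSE objective. The f_org target copy is
# detached: gradient reaches the fusion network only through the encoder
# input path, which rules out the trivial constant-output minimum.
model_backward <- function(model, fw, grads) {
  hw <- nrow(fw$f_rec)
  dfrec <- 2 * (unclass(fw$f_rec) - unclass(fw$f_org)) / hw
  denc <- decode_backward(model$theta, model$config, fw$caches$de, dfrec, grads)
  dforg <- encode_backward(model$theta, model$config, fw$caches$en, denc, grads)
  fusion_backward(model$theta, fw$caches$fus, model$resize_mats, dforg, grads)
  invisible(NULL)
}

#' Reconstruct a fused feature map
#'
#' Runs the neighbor-masked encoder and the layer-wise query decoder in
#' inference mode (dropout disabled).
#'
#' @param f_org a `fused_feature_map` (or `(H*W) x D` matrix).
#' @param model an `ad_model` whose grid matches `f_org`.
#' @return `f_rec`, a `fused_feature_map` of identical shape.
#' @export
reconstruct <- function(f_org, model) {
  check_flag(inherits(model, "ad_model"), "`model` must be an ad_model")
  check_flag(nrow(f_org) == prod(model$grid), "token count does not match the model grid")
  en <- encode(unclass(f_org), model$theta, model$config, model$mask)
  de <- decode(en$out, model$theta, model$config, mask = model$mask)
  fused_feature_map(de$out, model$grid[1], model$grid[2])
}

# Pipeline helpers ---------------------------------------------------------

image_to_rgb <- function(img) {
  px <- if (inherits(img, "ivcm_image")) img$pixels else img
  array(rep(as.numeric(px), 3L), dim = c(nrow(px), ncol(px), 3L))
}

model_pyramid <- function(model, img) {
  extract_pyramid(image_to_rgb(img), model$backbone)
}
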