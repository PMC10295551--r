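#' Compact convolutional transformer configuration
#'
#' One point in the architecture grid. The defaults describe the final
#' DR-CCTNet configuration: a two-stage bias-free convolutional tokenizer
#' (3 -> 64 -> 128 filters, kernel 3, stride 1, ReLU, max-pool kernel 3 /
#' stride 2, same padding), one transformer encoder block with 2-head
#' self-attention of per-head key width 128 and a single 128-unit MLP dense
#' layer, stochastic depth 0.1, sequence pooling, and a 5-class linear head
#' with softmax. No positional embedding is used, which makes the trainable
#' parameter count independent of the input image size.
#'
#' @param image_size Input side length in pixels (default 16).
#' @param conv_channels Filter counts of the tokenizer stages (default
#'   `c(64, 128)`); the last entry must equal `embed_dim`.
#' @param conv_kernel,conv_stride Tokenizer convolution kernel size and
#'   stride (defaults 3 and 1).
#' @param conv_bias Whether tokenizer convolutions carry bias terms
#'   (default `FALSE`).
#' @param pool_kernel,pool_stride Max-pool kernel and stride (defaults 3
#'   and 2).
#' @param num_encoder_blocks Number of transformer encoder blocks
#'   (default 1).
#' @param embed_dim Token embedding width d (default 128).
#' @param num_heads,head_key_dim Attention heads and per-head key width
#'   (defaults 2 and 128; the inner projection width is their product).
#' @param mlp_dense_layers Number of (dense 128 + activation + dropout)
#'   pairs in the encoder MLP (default 1).
#' @param mlp_activation One of `relu`, `tanh`, `elu`, `softsign`,
#'   `softplus`, `gelu` (default `relu`).
#' @param positional_embedding Whether to add a learnable positional
#'   embedding to the token sequence (default `FALSE`).
#' @param stochastic_depth_rate Probability of dropping each residual
#'   branch during training (default 0.1).
#' @param dropout_rate Dropout probability inside the encoder MLP
#'   (default 0.1).
#' @param num_classes Number of output grades (default 5).
#' @param seed Weight-initialization seed.
#' @return An object of class `cct_config`.
#' @export
cct_config <- function(image_size = 16, conv_channels = c(64, 128),
                       conv_kernel = 3, conv_stride = 1, conv_bias = FALSE,
                       pool_kernel = 3, pool_stride = 2,
                       num_encoder_blocks = 1, embed_dim = 128,
                       num_heads = 2, head_key_dim = 128,
                       mlp_dense_layers = 1,
                       mlp_activation = c("relu", "tanh", "elu", "softsign",
                                          "softplus", "gelu"),
                       positional_embedding = FALSE,
                       stochastic_depth_rate = 0.1, dropout_rate = 0.1,
                       num_classes = 5, seed = 42) {
  mlp_activation <- match.arg(mlp_activation)
  stopifnot(image_size >= 4, num_encoder_blocks >= 1, conv_kernel >= 1,
            conv_stride >= 1, pool_kernel >= 1, pool_stride >= 1,
            num_heads >= 1, head_key_dim >= 1, mlp_dense_layers >= 0,
            stochastic_depth_rate >= 0, stochastic_depth_rate <= 1,
            dropout_rate >= 0, dropout_rate < 1)
  if (utils::tail(conv_channels, 1) != embed_dim)
    stop("embed_dim must equal the last tokenizer filter count", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size),
    conv_channels = as.integer(conv_channels),
    conv_kernel = as.integer(conv_kernel), conv_stride = as.integer(conv_stride),
    conv_bias = isTRUE(conv_bias),
    pool_kernel = as.integer(pool_kernel), pool_stride = as.integer(pool_stride),
    num_encoder_blocks = as.integer(num_encoder_blocks),
    embed_dim = as.integer(embed_dim),
    num_heads = as.integer(num_heads), head_key_dim = as.integer(head_key_dim),
    mlp_dense_layers = as.integer(mlp_dense_layers),
    mlp_activation = mlp_activation,
    positional_embedding = isTRUE(positional_embedding),
    stochastic_depth_rate = stochastic_depth_rate,
    dropout_rate = dropout_rate,
    num_classes = as.integer(num_classes),
    seed = as.integer(seed)
  ), class = "cct_config")
}

#' @export
print.cct_config <- function(x, ...) {
  cat("Compact convolutional transformer configuration\n")
  cat(sprintf("  input %dx%dx3; tokenizer filters [%s], kernel %d, stride %d%s; pool %d/%d\n",
              x$image_size, x$image_size,
              paste(x$conv_channels, collapse = ", "),
              x$conv_kernel, x$conv_stride,
              if (x$conv_bias) "" else " (no bias)",
              x$pool_kernel, x$pool_stride))
  cat(sprintf("  %d encoder block(s): %d heads x key %d, %d MLP dense layer(s), %s\n",
              x$num_encoder_blocks, x$num_heads, x$head_key_dim,
              x$mlp_dense_layers, x$mlp_activation))
  cat(sprintf("  tokens %d x %d; positional embedding: %s; classes: %d\n",
              token_count(x), x$embed_dim,
              if (x$positional_embedding) "yes" else "no", x$num_classes))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Token sequence length for a configuration
#'
#' Spatial size after each tokenizer stage under same padding:
#' `ceil(s / conv_stride)` per convolution and `ceil(s / pool_stride)` per
#' pool, squared at the end (row-major flattening). With the defaults a
#' 16x16 input yields 16 tokens and a 32x32 input 64 tokens.
#'
#' @param cfg A [cct_config()].
#' @param image_size Input side length (defaults to `cfg$image_size`).
#' @return The number of tokens n.
#' @export
token_count <- function(cfg, image_size = cfg$image_size) {
  s <- image_size
  for (stage in seq_along(cfg$conv_channels)) {
    s <- ceiling(s / cfg$conv_stride)
    s <- ceiling(s / cfg$pool_stride)
  }
  as.integer(s)^2
}

#' Exact trainable-parameter count
#'
#' Sums the trainable scalars of the configured architecture analytically:
#' tokenizer convolutions `k^2 * c_in * c_out` (plus `c_out` biases when
#' enabled); per encoder block two layer norms (`2d` each), the attention
#' projections (`3 (d w + w)` for queries/keys/values with inner width
#' `w = heads * key_dim`, plus `w d + d` for the output projection) and
#' `mlp_dense_layers * (d^2 + d)`; the final layer norm (`2d`); the
#' sequence-pool scorer (`d + 1`); the classifier (`d c + c`); and, when
#' enabled, a positional embedding of `n * d`. For the default family this
#' reduces to `8384 k^2 + 150022`.
#'
#' @param cfg A [cct_config()].
#' @param image_size Input side length; only relevant when the positional
#'   embedding is enabled.
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg, image_size = cfg$image_size) {
  k <- cfg$conv_kernel; d <- cfg$embed_dim
  cins <- c(3L, cfg$conv_channels[-length(cfg$conv_channels)])
  conv <- sum(k^2 * cins * cfg$conv_channels) +
    if (cfg$conv_bias) sum(cfg$conv_channels) else 0L
  w <- cfg$num_heads * cfg$head_key_dim
  attn <- 3L * (d * w + w) + (w * d + d)
  block <- 2L * (2L * d) + attn + cfg$mlp_dense_layers * (d * d + d)
  pos <- if (cfg$positional_embedding) token_count(cfg, image_size) * d else 0L
  total <- conv + cfg$num_encoder_blocks * block + 2L * d + (d + 1L) +
    (d * cfg$num_classes + cfg$num_classes) + pos
  as.integer(total)
}
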