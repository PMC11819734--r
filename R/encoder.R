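# The single-channel convolutional encoder.
#
# A plain four-convolution CNN in the SOPCNN style: 3x3 same-padding
# convolutions with ReLU, channel ladder 1 -> 32 -> 64 -> 128 -> 256, 2x2
# max-pooling after the second and fourth convolutions (so the spatial side
# shrinks by 4 overall and the flatten length is channels * (side/4)^2), a
# 2048-unit fully connected layer with heavy dropout, and a final projection
# to the representation dimension.  It consumes exactly one channel — the
# contract the edge-magnitude augmentation pipelines guarantee.

#' Encoder configuration
#'
#' @param input_size Input side in pixels; must be divisible by 4 (two 2x2
#'   poolings).  112 is the default training resolution; 224 is also
#'   supported.
#' @param representation_dim Output embedding dimension (>= 2; default 64).
#' @param conv_channels Four-stage channel ladder.
#' @param fc_hidden Width of the fully connected layer before the projection.
#' @param dropout_p Dropout probability after the hidden layer.
#' @param seed Weight-initialisation seed.
#' @return An `encoder_config` object.
#' @export
encoder_config <- function(input_size = 112L, representation_dim = 64L,
                           conv_channels = c(32L, 64L, 128L, 256L),
                           fc_hidden = 2048L, dropout_p = 0.8, seed = 1L) {
  input_size <- as.integer(input_size)
  if (is.na(input_size) || input_size < 4L || input_size %% 4L != 0L) {
    stop("`input_size` must be a positive multiple of 4", call. = FALSE)
  }
  representation_dim <- as.integer(representation_dim)
  if (is.na(representation_dim) || representation_dim < 2L) {
    stop("`representation_dim` must be >= 2", call. = FALSE)
  }
  stopifnot(length(conv_channels) == 4L, all(conv_channels >= 1),
            fc_hidden >= 1, dropout_p >= 0, dropout_p < 1)
  structure(list(input_size = input_size,
                 representation_dim = representation_dim,
                 conv_channels = as.integer(conv_channels),
                 fc_hidden = as.integer(fc_hidden),
                 dropout_p = dropout_p, seed = as.integer(seed)),
            class = "encoder_config")
}

#' Flattened feature length of an encoder configuration
#'
#' `conv_channels[4] * (input_size / 4)^2`; e.g. 256 * 28 * 28 = 200,704 at
#' the default 112-pixel input.
#'
#' @param config An [encoder_config()].
#' @export
encoder_flat_dim <- function(config) {
  side <- config$input_size %/% 4L
  config$conv_channels[4L] * side * side
}

#' Trainable parameter count as a pure function of the configuration
#'
#' @param config An [encoder_config()].
#' @return Parameter count (double, since the default configuration exceeds
#'   the integer range comfortably).
#' @export
encoder_param_count <- function(config) {
  ch <- c(1, config$conv_channels)
  conv <- sum(ch[-length(ch)] * ch[-1] * 9 + ch[-1])
  flat <- encoder_flat_dim(config)
  fc1 <- as.numeric(flat) * config$fc_hidden + config$fc_hidden
  fc2 <- as.numeric(config$fc_hidden) * config$representation_dim +
    config$representation_dim
  conv + fc1 + fc2
}

#' Build the encoder
#'
#' @param config An [encoder_config()].
#' @return A `posture_encoder`: list with the layer stack (`net`) and the
#'   `config`.
#' @export
build_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  rng <- rng_new(config$seed)
  ch <- config$conv_channels
  layers <- list(
    layer_conv(1L, ch[1], rng), layer_relu(),
    layer_conv(ch[1], ch[2], rng), layer_relu(), layer_pool(),
    layer_conv(ch[2], ch[3], rng), layer_relu(),
    layer_conv(ch[3], ch[4], rng), layer_relu(), layer_pool(),
    layer_flatten(),
    layer_linear(encoder_flat_dim(config), config$fc_hidden, rng),
    layer_relu(),
    layer_dropout(config$dropout_p),
    layer_linear(config$fc_hidden, config$representation_dim, rng)
  )
  structure(list(net = list(layers = layers), config = config),
            class = "posture_encoder")
}

# stack a list of single-channel matrices (or an H x W x N array) into the
# (H, W, 1, N) batch layout, validating the channel/size contract
views_to_batch <- function(views, input_size) {
  if (is.array(views) && length(dim(views)) == 3L) {
    views <- lapply(seq_len(dim(views)[3L]), function(i) views[, , i])
  }
  if (is.matrix(views)) views <- list(views)
  n <- length(views)
  stopifnot(n >= 1L)
  x <- array(0, c(input_size, input_size, 1L, n))
  for (i in seq_len(n)) {
    v <- views[[i]]
    if (!is.matrix(v)) {
      stop("views must be single-channel matrices", call. = FALSE)
    }
    if (nrow(v) != input_size || ncol(v) != input_size) {
      stop("view ", i, " is ", nrow(v), "x", ncol(v),
           " but the encoder expects ", input_size, "x", input_size,
           call. = FALSE)
    }
    x[, , 1L, i] <- v
  }
  x
}

# L2-normalise the columns of an embedding matrix; epsilon guards the
# all-zero embeddings that heavy dropout can produce early in training
.l2_normalize_cols <- function(E, eps = 1e-12) {
  n <- sqrt(colSums(E^2))
  r <- n + eps
  list(Q = sweep(E, 2, r, "/"), norm = n, r = r)
}

# gradient of x -> x / (||x|| + eps) applied columnwise
.l2_normalize_cols_backward <- function(E, norm_info, dQ) {
  r <- norm_info$r; n <- norm_info$norm
  s <- colSums(E * dQ)
  sweep(dQ, 2, r, "/") - sweep(E, 2, s / (pmax(n, 1e-300) * r^2), "*")
}

#' Encode a batch of views
#'
#' Runs the encoder in inference mode (dropout disabled) and, by default,
#' L2-normalises each embedding to unit norm (the premise of the cosine
#' similarity the contrastive loss is built on).
#'
#' @param encoder A `posture_encoder`.
#' @param views List of single-channel `input_size` x `input_size` matrices,
#'   an `H x W x N` array, or a single matrix.
#' @param normalize L2-normalise rows of the output (default TRUE).
#' @return `n x representation_dim` matrix of embeddings with attribute
#'   `l2_normalized`.
#' @export
encode <- function(encoder, views, normalize = TRUE) {
  stopifnot(inherits(encoder, "posture_encoder"))
  x <- views_to_batch(views, encoder$config$input_size)
  out <- net_forward(encoder$net, x, train = FALSE)$out  # (d, N)
  if (normalize) out <- .l2_normalize_cols(out)$Q
  emb <- t(out)
  attr(emb, "l2_normalized") <- normalize
  emb
}

#' Save / load an encoder checkpoint
#'
#' Checkpoints carry the configuration, weights and an optional training
#' step counter.
#'
#' @param encoder A `posture_encoder`.
#' @param path File path.
#' @param step Optional training step to record.
#' @export
save_encoder <- function(encoder, path, step = NA_integer_) {
  saveRDS(list(config = unclass(encoder$config),
               params = net_params(encoder$net), step = step), path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  ck <- readRDS(path)
  config <- do.call(encoder_config, ck$config[setdiff(names(ck$config), NULL)])
  enc <- build_encoder(config)
  enc$net <- net_set_params(enc$net, ck$params)
  attr(enc, "step") <- ck$step
  enc
}
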