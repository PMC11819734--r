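# Momentum-contrast pretraining.
#
# Two copies of the encoder: the query encoder is trained by SGD on an
# InfoNCE / NT-Xent objective; the key (momentum) encoder is an exponential
# moving average of the query encoder's parameters and supplies positives,
# while a FIFO queue of past key embeddings supplies the negatives.  The
# printed batch-form NT-Xent loss and the queue-based InfoNCE loss are both
# implemented; they coincide when the "batch" is taken to be
# {query, positive key} united with the queue, which is the identity the
# test suite verifies numerically.

.check_unit <- function(z, what = "embedding", tol = 1e-3) {
  n <- sqrt(sum(z^2))
  if (abs(n - 1) > tol) {
    stop(what, " must be unit-norm (got norm ", format(n), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cosine similarity of two unit-norm embeddings
#'
#' For unit vectors the cosine similarity reduces to the dot product; inputs
#' whose norm deviates from 1 by more than 1e-3 are rejected.
#'
#' @param z_i,z_j Unit-norm numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(z_i, z_j) {
  stopifnot(length(z_i) == length(z_j))
  .check_unit(z_i, "z_i"); .check_unit(z_j, "z_j")
  min(max(sum(z_i * z_j), -1), 1)
}

#' Batch-form NT-Xent loss for one positive pair
#'
#' The normalized temperature-scaled cross-entropy for a positive pair
#' (i, j) within a batch of embeddings:
#' `-log( exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) )`.
#' This is the reference/oracle form; training itself uses the queue-based
#' [moco_infonce_loss()], which equals this form under the
#' {query, key} + queue batch construction.
#'
#' @param i,j Row indices of the positive pair in `batch_embeddings`.
#' @param batch_embeddings Matrix with unit-norm embeddings in rows.
#' @param tau Temperature (> 0).
#' @return Scalar loss.
#' @export
nt_xent_pair_loss <- function(i, j, batch_embeddings, tau = 0.07) {
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  M <- nrow(batch_embeddings)
  stopifnot(i >= 1, i <= M, j >= 1, j <= M, i != j)
  norms <- sqrt(rowSums(batch_embeddings^2))
  if (any(abs(norms - 1) > 1e-3)) {
    stop("batch embeddings must be unit-norm", call. = FALSE)
  }
  sims <- as.vector(batch_embeddings %*% batch_embeddings[i, ]) / tau
  others <- sims[-i]
  m <- max(others)
  lse <- m + log(sum(exp(others - m)))
  -(sims[j] - lse)
}

#' Queue-based InfoNCE loss for one query
#'
#' `-log( exp(q.k+/tau) / (exp(q.k+/tau) + sum_neg exp(q.k-/tau)) )` with
#' the negatives read from the key queue.
#'
#' @param query,key_positive Unit-norm vectors.
#' @param queue A `queue_state` with at least one stored key, or a matrix of
#'   negative keys in columns.
#' @param tau Temperature (> 0).
#' @return Scalar loss.
#' @export
moco_infonce_loss <- function(query, key_positive, queue, tau = 0.07) {
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  .check_unit(query, "query"); .check_unit(key_positive, "key_positive")
  negs <- if (inherits(queue, "queue_state")) queue_keys(queue) else queue
  if (is.null(dim(negs)) || ncol(negs) < 1L) {
    stop("queue is empty: the InfoNCE denominator needs at least one negative",
         call. = FALSE)
  }
  stopifnot(nrow(negs) == length(query))
  logits <- c(sum(query * key_positive), as.vector(crossprod(negs, query))) / tau
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  -(logits[1L] - lse)
}

# Batched InfoNCE loss and its gradient w.r.t. the normalised queries.
# Q, Kpos: (d, N) unit-norm columns; negs: (d, K).
.infonce_batch <- function(Q, Kpos, negs, tau) {
  N <- ncol(Q)
  l_pos <- colSums(Q * Kpos) / tau               # (N)
  l_neg <- crossprod(negs, Q) / tau              # (K, N)
  logits <- rbind(l_pos, l_neg)                  # (1+K, N)
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx, "-"))
  Z <- colSums(ex)
  p <- sweep(ex, 2, Z, "/")
  loss <- mean(-(l_pos - (mx + log(Z))))
  dQ <- (sweep(Kpos, 2, p[1L, ] - 1, "*") +
           negs %*% p[-1L, , drop = FALSE]) / (tau * N)
  list(loss = loss, dQ = dQ)
}

#' Exponential-moving-average (momentum) parameter update
#'
#' Each key parameter becomes `m * key + (1 - m) * query`.  `m = 1` leaves
#' the key encoder untouched; `m = 0` copies the query encoder.
#'
#' @param query_params,key_params Congruent (possibly nested) lists of
#'   numeric arrays, e.g. from two encoder copies.
#' @param m Momentum coefficient in \[0, 1\].
#' @return Updated key parameters with the same structure.
#' @export
momentum_update <- function(query_params, key_params, m = 0.999) {
  if (m < 0 || m > 1) stop("`m` must be in [0, 1]", call. = FALSE)
  upd <- function(q, k) {
    if (is.list(q) && is.list(k)) {
      stopifnot(length(q) == length(k))
      return(mapply(upd, q, k, SIMPLIFY = FALSE))
    }
    if (!identical(dim(q), dim(k)) || length(q) != length(k)) {
      stop("parameter shapes do not match", call. = FALSE)
    }
    m * k + (1 - m) * q
  }
  upd(query_params, key_params)
}

# ---- key queue -------------------------------------------------------------

#' FIFO queue of key embeddings
#'
#' A ring buffer of up to `capacity` unit-norm key embeddings (columns).
#' `init = "random"` warm-starts the queue with random unit vectors so the
#' InfoNCE denominator is well-defined from the first step;
#' `init = "empty"` grows until full instead.
#'
#' @param dim Embedding dimension.
#' @param capacity Maximum number of stored keys.
#' @param init `"random"` or `"empty"`.
#' @param rng Generator for the random warm start.
#' @return A `queue_state`: list with `keys` (`dim x capacity`), `fill`,
#'   `pointer` (0-based next write slot), `capacity`.
#' @export
queue_init <- function(dim, capacity, init = c("random", "empty"),
                       rng = NULL) {
  init <- match.arg(init)
  stopifnot(dim >= 1, capacity >= 1)
  keys <- matrix(0, dim, capacity)
  fill <- 0L
  if (init == "random") {
    if (is.null(rng)) rng <- rng_new(0L)
    keys <- matrix(rng_rnorm(rng, dim * capacity), dim, capacity)
    keys <- sweep(keys, 2, sqrt(colSums(keys^2)), "/")
    fill <- as.integer(capacity)
  }
  structure(list(keys = keys, dim = as.integer(dim),
                 capacity = as.integer(capacity),
                 fill = fill, pointer = 0L),
            class = "queue_state")
}

#' Enqueue a batch of keys, evicting the oldest on overflow
#'
#' @param queue A `queue_state`.
#' @param new_keys Matrix of unit-norm keys in columns (`dim x B`), or a
#'   single vector.
#' @return The updated `queue_state`.
#' @export
enqueue <- function(queue, new_keys) {
  stopifnot(inherits(queue, "queue_state"))
  if (is.null(dim(new_keys))) new_keys <- matrix(new_keys, ncol = 1L)
  if (nrow(new_keys) != queue$dim) {
    stop("key dimension ", nrow(new_keys), " does not match queue dimension ",
         queue$dim, call. = FALSE)
  }
  norms <- sqrt(colSums(new_keys^2))
  if (any(abs(norms - 1) > 1e-3)) {
    stop("keys must be unit-norm before enqueueing", call. = FALSE)
  }
  B <- ncol(new_keys)
  K <- queue$capacity
  if (B >= K) {
    queue$keys <- new_keys[, (B - K + 1L):B, drop = FALSE]
    queue$fill <- K
    queue$pointer <- 0L
    return(queue)
  }
  slots <- ((queue$pointer + seq_len(B) - 1L) %% K) + 1L
  queue$keys[, slots] <- new_keys
  queue$pointer <- (queue$pointer + B) %% K
  queue$fill <- min(K, queue$fill + B)
  queue
}

#' @rdname queue_init
#' @param queue A `queue_state`.
#' @return `queue_keys()` returns the currently stored keys as a
#'   `dim x fill` matrix.
#' @export
queue_keys <- function(queue) {
  stopifnot(inherits(queue, "queue_state"))
  queue$keys[, seq_len(queue$fill), drop = FALSE]
}

# ---- training --------------------------------------------------------------

#' Contrastive pretraining configuration
#'
#' Defaults are the published training hyperparameters: temperature 0.07,
#' key-encoder momentum 0.999, queue capacity 65,536, batch size 32, 2000
#' epochs, SGD with learning rate 1e-4, momentum 0.9 and weight decay 1e-4,
#' 64-dimensional representations.  The queue default far exceeds a
#' few-thousand-image corpus; scale it down for desk-size runs.
#'
#' @param temperature Softmax temperature tau (> 0).
#' @param momentum EMA coefficient m for the key encoder, in \[0, 1\].
#' @param queue_capacity Number of negative keys kept (>= batch_size).
#' @param batch_size Images per step.
#' @param epochs Passes through the pretraining set.
#' @param learning_rate,optimizer_momentum,weight_decay SGD parameters.
#' @param queue_init `"random"` warm start or `"empty"` grow-until-full.
#' @param seed Seed for shuffling, augmentation draws, dropout and the queue
#'   warm start.
#' @return A `contrastive_config` object.
#' @export
contrastive_config <- function(temperature = 0.07, momentum = 0.999,
                               queue_capacity = 65536L, batch_size = 32L,
                               epochs = 2000L, learning_rate = 1e-4,
                               optimizer_momentum = 0.9, weight_decay = 1e-4,
                               queue_init = "random", seed = 1L) {
  if (temperature <= 0) stop("`temperature` must be > 0", call. = FALSE)
  if (momentum < 0 || momentum > 1) {
    stop("`momentum` must be in [0, 1]", call. = FALSE)
  }
  if (queue_capacity < batch_size) {
    stop("`queue_capacity` must be >= `batch_size`", call. = FALSE)
  }
  stopifnot(batch_size >= 2, epochs >= 1, learning_rate > 0)
  structure(list(temperature = temperature, momentum = momentum,
                 queue_capacity = as.integer(queue_capacity),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 optimizer_momentum = optimizer_momentum,
                 weight_decay = weight_decay,
                 queue_init = queue_init,
                 seed = as.integer(seed)),
            class = "contrastive_config")
}

#' Momentum-contrast pretraining
#'
#' Per step: draw a query/key view pair for every image in the batch, encode
#' queries with the trainable encoder (dropout active) and keys with the
#' momentum encoder (inference mode, no gradient), L2-normalise both,
#' compute the queue-based InfoNCE loss, take an SGD step on the query
#' encoder, EMA-update the key encoder, and enqueue the new keys.  The key
#' encoder starts as a copy of the query encoder.
#'
#' @param images List of grayscale image matrices (the pretraining split).
#' @param augment_cfg An [augment_config()] whose `size` matches the encoder
#'   input.
#' @param encoder_cfg An [encoder_config()].
#' @param contrastive_cfg A [contrastive_config()].
#' @param verbose Print per-epoch mean loss.
#' @return List with `encoder` (trained query encoder), `key_encoder`,
#'   `queue`, and `record` (a `train_run_record`: config snapshots,
#'   per-epoch mean loss, seeds).
#' @export
pretrain <- function(images, augment_cfg, encoder_cfg, contrastive_cfg,
                     verbose = FALSE) {
  if (length(images) == 0L) {
    stop("the pretraining split is empty", call. = FALSE)
  }
  stopifnot(inherits(augment_cfg, "augment_config"),
            inherits(encoder_cfg, "encoder_config"),
            inherits(contrastive_cfg, "contrastive_config"))
  if (augment_cfg$size != encoder_cfg$input_size) {
    stop("augmentation size (", augment_cfg$size,
         ") must match encoder input size (", encoder_cfg$input_size, ")",
         call. = FALSE)
  }
  cfg <- contrastive_cfg
  master <- rng_new(cfg$seed)
  aug_rng <- rng_new(rng_child_seed(master))
  drop_rng <- rng_new(rng_child_seed(master))
  order_rng <- rng_new(rng_child_seed(master))
  queue_rng <- rng_new(rng_child_seed(master))

  qnet <- build_encoder(encoder_cfg)$net
  knet <- qnet  # key encoder initialised as a copy of the query encoder
  d <- encoder_cfg$representation_dim
  queue <- queue_init(d, cfg$queue_capacity, cfg$queue_init, queue_rng)
  opt_state <- sgd_state_init(qnet)

  n <- length(images)
  loss_hist <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- rng_sample(order_rng, n)
    losses <- c()
    b0 <- 1L
    while (b0 <= n) {
      b1 <- min(b0 + cfg$batch_size - 1L, n)
      idx <- ord[b0:b1]
      b0 <- b1 + 1L
      if (length(idx) < 2L) next
      B <- length(idx)
      S <- encoder_cfg$input_size
      xq <- array(0, c(S, S, 1L, B))
      xk <- array(0, c(S, S, 1L, B))
      for (bi in seq_len(B)) {
        vp <- two_crops(images[[idx[bi]]], augment_cfg, aug_rng)
        xq[, , 1L, bi] <- vp$query_view
        xk[, , 1L, bi] <- vp$key_view
      }
      fq <- net_forward(qnet, xq, train = TRUE, rng = drop_rng)
      qnet <- fq$net
      nq <- .l2_normalize_cols(fq$out)
      fk <- net_forward(knet, xk, train = FALSE)
      Kpos <- .l2_normalize_cols(fk$out)$Q
      if (queue$fill < 1L) {
        # grow-until-full mode before any key exists: seed with this batch
        queue <- enqueue(queue, Kpos)
        next
      }
      lb <- .infonce_batch(nq$Q, Kpos, queue_keys(queue), cfg$temperature)
      losses <- c(losses, lb$loss)
      dE <- .l2_normalize_cols_backward(fq$out, nq, lb$dQ)
      grads <- net_backward(qnet, fq$caches, dE)$grads
      st <- sgd_step(qnet, grads, opt_state, cfg$learning_rate,
                     cfg$optimizer_momentum, cfg$weight_decay)
      qnet <- st$net
      opt_state <- st$state
      knet <- net_set_params(knet, momentum_update(net_params(qnet),
                                                   net_params(knet),
                                                   cfg$momentum))
      queue <- enqueue(queue, Kpos)
    }
    loss_hist[epoch] <- if (length(losses)) mean(losses) else NA_real_
    if (verbose) {
      message(sprintf("epoch %d/%d  mean loss %.4f", epoch, cfg$epochs,
                      loss_hist[epoch]))
    }
  }
  encoder <- structure(list(net = qnet, config = encoder_cfg),
                       class = "posture_encoder")
  key_encoder <- structure(list(net = knet, config = encoder_cfg),
                           class = "posture_encoder")
  record <- structure(list(contrastive_config = unclass(cfg),
                           encoder_config = unclass(encoder_cfg),
                           augment_config = unclass(augment_cfg),
                           loss_history = loss_hist,
                           n_images = n, seed = cfg$seed),
                      class = "train_run_record")
  list(encoder = encoder, key_encoder = key_encoder, queue = queue,
       record = record)
}
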