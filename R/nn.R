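# Minimal neural-network core.
#
# No deep-learning framework ships with the R stack this package targets, so
# the few layer types the encoder and classifier head need are implemented
# here directly: 3x3 same-padding convolution (via im2col + BLAS matmul),
# ReLU, 2x2 max-pooling, flatten, fully connected, inverted dropout and 1-D
# batch normalisation, plus SGD with momentum and weight decay.  Everything
# is functional: forward passes return updated nets (batch-norm running
# statistics), and all randomness flows through explicit rng objects.  Every
# backward pass is checked against central finite differences in the test
# suite.
#
# Batch tensors are arrays with dim (H, W, C, N); feature matrices are
# (features, N) with samples in columns.

# ---- layer constructors ----------------------------------------------------

# fan-in-scaled uniform init, the standard scheme for conv/linear layers
.init_mat <- function(nrow_, ncol_, fan_in, rng) {
  bound <- 1 / sqrt(fan_in)
  matrix(rng_runif(rng, nrow_ * ncol_, -bound, bound), nrow_, ncol_)
}

layer_conv <- function(in_ch, out_ch, rng, k = 3L, pad = 1L) {
  fan_in <- in_ch * k * k
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k, pad = pad,
       params = list(W = .init_mat(out_ch, fan_in, fan_in, rng),
                     b = rng_runif(rng, out_ch, -1 / sqrt(fan_in), 1 / sqrt(fan_in))))
}

layer_linear <- function(in_f, out_f, rng) {
  list(type = "linear", in_f = in_f, out_f = out_f,
       params = list(W = .init_mat(out_f, in_f, in_f, rng),
                     b = rng_runif(rng, out_f, -1 / sqrt(in_f), 1 / sqrt(in_f))))
}

layer_relu <- function() list(type = "relu", params = list())
layer_pool <- function() list(type = "pool", params = list())
layer_flatten <- function() list(type = "flatten", params = list())
layer_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  list(type = "dropout", p = p, params = list())
}
layer_batchnorm <- function(n_f, eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm", n_f = n_f, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, n_f), beta = rep(0, n_f)),
       buffers = list(running_mean = rep(0, n_f), running_var = rep(1, n_f)))
}

# ---- im2col ----------------------------------------------------------------

.pad_zeros <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# columns of the patch matrix are ordered (row index fastest, then column,
# then sample); rows are ordered (kernel row offset fastest, then kernel
# column offset, then input channel)
.im2col <- function(xp, H, W, C, N, k) {
  Hp <- dim(xp)[1]; Wp <- dim(xp)[2]
  ab <- expand.grid(a = 0:(k - 1), b = 0:(k - 1))
  rowoff <- rep(ab$a + Hp * ab$b, times = C) +
    rep((0:(C - 1)) * Hp * Wp, each = k * k)
  colbase <- as.vector(outer(seq_len(H), (0:(W - 1)) * Hp, "+"))
  lin <- outer(rowoff, colbase, "+")
  per_sample <- Hp * Wp * C
  idx <- rep(as.vector(lin), N) +
    rep((0:(N - 1)) * per_sample, each = length(lin))
  matrix(xp[idx], k * k * C, H * W * N)
}

# ---- forward ----------------------------------------------------------------

.fwd_conv <- function(layer, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  stopifnot(C == layer$in_ch)
  xp <- .pad_zeros(x, layer$pad)
  cols <- .im2col(xp, H, W, C, N, layer$k)
  out_mat <- layer$params$W %*% cols + layer$params$b
  out <- aperm(array(out_mat, c(layer$out_ch, H, W, N)), c(2, 3, 1, 4))
  list(out = out, cache = list(cols = cols, H = H, W = W, C = C, N = N))
}

.bwd_conv <- function(layer, cache, dout) {
  H <- cache$H; W <- cache$W; C <- cache$C; N <- cache$N
  k <- layer$k; p <- layer$pad
  dout_mat <- matrix(aperm(dout, c(3, 1, 2, 4)), layer$out_ch, H * W * N)
  dW <- dout_mat %*% t(cache$cols)
  db <- rowSums(dout_mat)
  dcols <- crossprod(layer$params$W, dout_mat)
  Hp <- H + 2 * p; Wp <- W + 2 * p
  dpad <- array(0, c(Hp, Wp, C, N))
  ab <- expand.grid(a = 0:(k - 1), b = 0:(k - 1))
  for (t_ in seq_len(k * k)) {
    a <- ab$a[t_]; b <- ab$b[t_]
    rows <- t_ + (0:(C - 1)) * (k * k)
    dsel <- dcols[rows, , drop = FALSE]
    arr <- aperm(array(dsel, c(C, H, W, N)), c(2, 3, 1, 4))
    dpad[a + seq_len(H), b + seq_len(W), , ] <-
      dpad[a + seq_len(H), b + seq_len(W), , , drop = FALSE] + arr
  }
  dx <- dpad[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

.fwd_pool <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  i1 <- seq(1, d[1], 2); i2 <- i1 + 1
  j1 <- seq(1, d[2], 2); j2 <- j1 + 1
  x11 <- x[i1, j1, , , drop = FALSE]; x21 <- x[i2, j1, , , drop = FALSE]
  x12 <- x[i1, j2, , , drop = FALSE]; x22 <- x[i2, j2, , , drop = FALSE]
  m <- pmax(x11, x21, x12, x22)
  g11 <- x11 == m
  g21 <- (x21 == m) & !g11
  g12 <- (x12 == m) & !g11 & !g21
  g22 <- !(g11 | g21 | g12)
  list(out = m, cache = list(g = list(g11, g21, g12, g22), dims = d))
}

.bwd_pool <- function(cache, dout) {
  d <- cache$dims
  dx <- array(0, d)
  i1 <- seq(1, d[1], 2); i2 <- i1 + 1
  j1 <- seq(1, d[2], 2); j2 <- j1 + 1
  g <- cache$g
  dx[i1, j1, , ] <- dout * g[[1]]
  dx[i2, j1, , ] <- dout * g[[2]]
  dx[i1, j2, , ] <- dout * g[[3]]
  dx[i2, j2, , ] <- dout * g[[4]]
  dx
}

.fwd_batchnorm <- function(layer, x, train) {
  eps <- layer$eps
  if (train) {
    N <- ncol(x)
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc^2)
    ivar <- 1 / sqrt(v + eps)
    xhat <- xc * ivar
    out <- layer$params$gamma * xhat + layer$params$beta
    mom <- layer$momentum
    ub <- if (N > 1) N / (N - 1) else 1
    layer$buffers$running_mean <- (1 - mom) * layer$buffers$running_mean + mom * mu
    layer$buffers$running_var <- (1 - mom) * layer$buffers$running_var + mom * v * ub
    list(out = out, cache = list(xhat = xhat, ivar = ivar), layer = layer)
  } else {
    xhat <- (x - layer$buffers$running_mean) /
      sqrt(layer$buffers$running_var + eps)
    out <- layer$params$gamma * xhat + layer$params$beta
    list(out = out, cache = NULL, layer = layer)
  }
}

.bwd_batchnorm <- function(layer, cache, dout) {
  xhat <- cache$xhat; ivar <- cache$ivar
  N <- ncol(dout)
  dgamma <- rowSums(dout * xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * layer$params$gamma
  dx <- (ivar / N) * (N * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

#' Forward pass through a layer stack
#'
#' @param net List with element `layers`.
#' @param x Input batch: `(H, W, C, N)` array for convolutional stacks or a
#'   `(features, N)` matrix for dense stacks.
#' @param train Training mode: enables dropout and batch-statistics
#'   normalisation.
#' @param rng Generator for dropout masks (required when training with
#'   dropout).
#' @return List with `out`, per-layer `caches`, and the (possibly updated)
#'   `net`.
#' @keywords internal
net_forward <- function(net, x, train = FALSE, rng = NULL) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    r <- switch(ly$type,
      conv = .fwd_conv(ly, x),
      linear = list(out = ly$params$W %*% x + ly$params$b,
                    cache = list(x = x)),
      relu = {
        mask <- x > 0
        list(out = x * mask, cache = list(mask = mask))
      },
      pool = .fwd_pool(x),
      flatten = {
        d <- dim(x)
        list(out = matrix(x, prod(d[1:3]), d[4]), cache = list(dims = d))
      },
      dropout = {
        if (train && ly$p > 0) {
          if (is.null(rng)) stop("dropout needs an rng in training mode",
                                 call. = FALSE)
          keep <- (rng_runif(rng, length(x)) >= ly$p) / (1 - ly$p)
          dim(keep) <- dim(x)
          list(out = x * keep, cache = list(keep = keep))
        } else {
          list(out = x, cache = list(keep = NULL))
        }
      },
      batchnorm = .fwd_batchnorm(ly, x, train),
      stop("unknown layer type: ", ly$type)
    )
    if (!is.null(r$layer)) net$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches, net = net)
}

#' Backward pass; returns per-layer parameter gradients
#'
#' @param net The net that produced the forward caches.
#' @param caches Caches from [net_forward()] (training mode).
#' @param dout Gradient of the loss w.r.t. the stack output.
#' @return List with `grads` (per-layer lists, shapes matching params) and
#'   `dx`.
#' @keywords internal
net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "conv") {
      r <- .bwd_conv(ly, ca, dout)
      grads[[i]] <- r$grads; dout <- r$dx
    } else if (ly$type == "linear") {
      grads[[i]] <- list(W = dout %*% t(ca$x), b = rowSums(dout))
      dout <- crossprod(ly$params$W, dout)
    } else if (ly$type == "relu") {
      grads[[i]] <- list(); dout <- dout * ca$mask
    } else if (ly$type == "pool") {
      grads[[i]] <- list(); dout <- .bwd_pool(ca, dout)
    } else if (ly$type == "flatten") {
      grads[[i]] <- list(); dout <- array(dout, ca$dims)
    } else if (ly$type == "dropout") {
      grads[[i]] <- list()
      if (!is.null(ca$keep)) dout <- dout * ca$keep
    } else if (ly$type == "batchnorm") {
      r <- .bwd_batchnorm(ly, ca, dout)
      grads[[i]] <- r$grads; dout <- r$dx
    }
  }
  list(grads = grads, dx = dout)
}

# ---- parameter plumbing ----------------------------------------------------

#' Extract / replace the trainable parameters of a net
#' @keywords internal
net_params <- function(net) lapply(net$layers, function(ly) ly$params)

#' @rdname net_params
#' @keywords internal
net_set_params <- function(net, params) {
  stopifnot(length(params) == length(net$layers))
  for (i in seq_along(params)) net$layers[[i]]$params <- params[[i]]
  net
}

#' Total number of trainable scalars in a net
#' @keywords internal
net_param_count <- function(net) {
  sum(vapply(net_params(net), function(p) sum(vapply(p, length, 1L)), 1))
}

# ---- optimiser -------------------------------------------------------------

sgd_state_init <- function(net) {
  lapply(net_params(net), function(p) lapply(p, function(w) w * 0))
}

# classic SGD with momentum: v <- mu v + (g + wd p); p <- p - lr v
sgd_step <- function(net, grads, state, lr, momentum = 0.9, weight_decay = 0) {
  params <- net_params(net)
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]] + weight_decay * params[[i]][[nm]]
      state[[i]][[nm]] <- momentum * state[[i]][[nm]] + g
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * state[[i]][[nm]]
    }
  }
  list(net = net_set_params(net, params), state = state)
}
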