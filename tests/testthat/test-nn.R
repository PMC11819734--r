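# The layer stack is hand-written, so its arithmetic is verified against
# independent oracles: a direct-loop convolution and central finite
# differences for every parameterised layer.

naive_conv3 <- function(x, W, b) {
  # x: (H, W, C) single sample; W: (Cout, 9C) with rows of x-patches ordered
  # (kernel row offset fastest, then column offset, then channel)
  H <- dim(x)[1]; W_ <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2, W_ + 2, C))
  xp[2:(H + 1), 2:(W_ + 1), ] <- x
  out <- array(0, c(H, W_, nrow(W)))
  for (i in 1:H) for (j in 1:W_) {
    patch <- numeric(0)
    for (c_ in 1:C) for (bb in 0:2) for (aa in 0:2) {
      patch <- c(patch, xp[i + aa, j + bb, c_])
    }
    out[i, j, ] <- W %*% patch + b
  }
  out
}

test_that("vectorised convolution equals the direct-loop oracle", {
  rng <- rng_new(21L)
  ly <- equimoco:::layer_conv(2L, 3L, rng)
  x <- array(rng_rnorm(rng, 5 * 6 * 2 * 2), c(5, 6, 2, 2))
  out <- equimoco:::net_forward(list(layers = list(ly)), x)$out
  for (n in 1:2) {
    expect_equal(out[, , , n], naive_conv3(x[, , , n], ly$params$W,
                                           ly$params$b),
                 tolerance = 1e-12)
  }
})

test_that("max pooling picks the 2x2 block maxima and routes gradients back", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  f <- equimoco:::.fwd_pool(x)
  expect_equal(as.vector(f$out), c(6, 8, 14, 16))
  dout <- array(1, c(2, 2, 1, 1))
  dx <- equimoco:::.bwd_pool(f$cache, dout)
  # gradient lands only on the argmax cells
  expect_equal(sum(dx), 4)
  expect_equal(dx[2, 2, 1, 1], 1)
  expect_equal(dx[1, 1, 1, 1], 0)
})

test_that("backpropagation matches finite differences through a conv stack", {
  rng <- rng_new(31L)
  net <- list(layers = list(
    equimoco:::layer_conv(1L, 3L, rng), equimoco:::layer_relu(),
    equimoco:::layer_pool(),
    equimoco:::layer_conv(3L, 4L, rng), equimoco:::layer_relu(),
    equimoco:::layer_pool(),
    equimoco:::layer_flatten(),
    equimoco:::layer_linear(4L * 2L * 2L, 5L, rng)))
  x <- array(rng_rnorm(rng, 8 * 8 * 1 * 3), c(8, 8, 1, 3))
  tgt <- matrix(rng_rnorm(rng, 5 * 3), 5, 3)
  loss_of <- function(nn) {
    o <- equimoco:::net_forward(nn, x)$out
    0.5 * sum((o - tgt)^2)
  }
  f <- equimoco:::net_forward(net, x)
  bk <- equimoco:::net_backward(net, f$caches, f$out - tgt)
  eps <- 1e-6
  for (li in seq_along(net$layers)) {
    for (nm in names(net$layers[[li]]$params)) {
      p <- net$layers[[li]]$params[[nm]]
      picks <- unique(round(seq(1, length(p), length.out = 6)))
      for (t_ in picks) {
        np <- net; np$layers[[li]]$params[[nm]][t_] <- p[t_] + eps
        nm_ <- net; nm_$layers[[li]]$params[[nm]][t_] <- p[t_] - eps
        fd <- (loss_of(np) - loss_of(nm_)) / (2 * eps)
        expect_equal(bk$grads[[li]][[nm]][t_], fd, tolerance = 1e-5)
      }
    }
  }
  # input gradient
  for (t_ in c(1, 17, 100)) {
    xp <- x; xp[t_] <- x[t_] + eps
    xm <- x; xm[t_] <- x[t_] - eps
    op <- equimoco:::net_forward(net, xp)$out
    om <- equimoco:::net_forward(net, xm)$out
    fd <- (0.5 * sum((op - tgt)^2) - 0.5 * sum((om - tgt)^2)) / (2 * eps)
    expect_equal(bk$dx[t_], fd, tolerance = 1e-5)
  }
})

test_that("batch-norm training gradients match finite differences", {
  rng <- rng_new(41L)
  net <- list(layers = list(
    equimoco:::layer_linear(6L, 4L, rng), equimoco:::layer_batchnorm(4L),
    equimoco:::layer_relu(), equimoco:::layer_linear(4L, 3L, rng)))
  x <- matrix(rng_rnorm(rng, 30), 6, 5)
  y <- c(1L, 3L, 2L, 1L, 2L)
  loss_of <- function(nn) {
    o <- equimoco:::net_forward(nn, x, train = TRUE)$out
    equimoco:::.softmax_ce(o, y)$loss
  }
  f <- equimoco:::net_forward(net, x, train = TRUE)
  ce <- equimoco:::.softmax_ce(f$out, y)
  bk <- equimoco:::net_backward(f$net, f$caches, ce$dlogits)
  eps <- 1e-6
  for (li in seq_along(net$layers)) {
    for (nm in names(net$layers[[li]]$params)) {
      p <- net$layers[[li]]$params[[nm]]
      for (t_ in seq_along(p)) {
        np <- net; np$layers[[li]]$params[[nm]][t_] <- p[t_] + eps
        nm_ <- net; nm_$layers[[li]]$params[[nm]][t_] <- p[t_] - eps
        fd <- (loss_of(np) - loss_of(nm_)) / (2 * eps)
        expect_equal(bk$grads[[li]][[nm]][t_], fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("dropout is identity at inference and unbiased in training", {
  rng <- rng_new(51L)
  net <- list(layers = list(equimoco:::layer_dropout(0.4)))
  x <- matrix(1, 50, 40)
  expect_identical(equimoco:::net_forward(net, x, train = FALSE)$out, x)
  o <- equimoco:::net_forward(net, x, train = TRUE, rng = rng)$out
  kept <- o[o > 0]
  expect_true(all(abs(kept - 1 / 0.6) < 1e-12))  # inverted scaling
  expect_lt(abs(mean(o) - 1), 0.05)              # unbiased expectation
})

test_that("batch-norm inference uses running statistics", {
  rng <- rng_new(61L)
  net <- list(layers = list(equimoco:::layer_batchnorm(3L)))
  x <- matrix(rng_rnorm(rng, 3 * 200, mean = 2, sd = 3), 3, 200)
  f <- equimoco:::net_forward(net, x, train = TRUE)
  # after one large batch the running stats move toward the batch stats
  upd <- f$net$layers[[1]]$buffers
  expect_equal(upd$running_mean, 0.9 * 0 + 0.1 * rowMeans(x),
               tolerance = 1e-12)
  # eval mode on the updated net is deterministic
  o1 <- equimoco:::net_forward(f$net, x, train = FALSE)$out
  o2 <- equimoco:::net_forward(f$net, x, train = FALSE)$out
  expect_identical(o1, o2)
})
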