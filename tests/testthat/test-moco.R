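test_that("cosine similarity follows the unit-vector identities", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_identical(cosine_similarity(e1, e1), 1)
  expect_identical(cosine_similarity(e1, e2), 0)
  expect_identical(cosine_similarity(e1, -e1), -1)
  expect_error(cosine_similarity(c(2, 0, 0), e1), "unit-norm")
})

test_that("NT-Xent closed forms evaluate exactly", {
  # batch of two: after excluding i the denominator is just the positive
  z <- rbind(c(1, 0), c(0, 1))
  expect_equal(nt_xent_pair_loss(1, 2, z, tau = 0.5), 0, tolerance = 1e-12)

  # batch of 4: sim(i,j) = 1, both other similarities 0, tau = 1
  z4 <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(nt_xent_pair_loss(1, 2, z4, tau = 1),
               log(1 + 2 * exp(-1)), tolerance = 1e-12)

  expect_error(nt_xent_pair_loss(1, 2, z4, tau = 0), "tau")
})

test_that("NT-Xent strictly decreases as the positive similarity grows", {
  # move z_j toward z_i on the unit circle, other batch members fixed
  fixed <- rbind(c(0, 1, 0), c(0, 0, 1))
  last <- Inf
  for (theta in seq(pi / 2, 0.05, length.out = 8)) {
    z <- rbind(c(1, 0, 0), c(cos(theta), sin(theta), 0), fixed)
    l <- nt_xent_pair_loss(1, 2, z, tau = 0.3)
    expect_lt(l, last)
    last <- l
  }
})

test_that("queue-based InfoNCE closed forms evaluate exactly", {
  d <- 16L
  q <- c(1, rep(0, d - 1))
  # K orthogonal negatives, tau = 1, q = k+
  K <- 8L
  negs <- diag(d)[, 2:(K + 1)]
  expect_equal(moco_infonce_loss(q, q, negs, tau = 1),
               log(1 + K * exp(-1)), tolerance = 1e-12)

  # one negative identical to the positive: probability 1/2
  expect_equal(moco_infonce_loss(q, q, matrix(q, ncol = 1), tau = 0.07),
               log(2), tolerance = 1e-12)

  # tau -> 0+ with the positive dominating: loss vanishes
  rng <- rng_new(15L)
  kpos <- c(sqrt(0.9), sqrt(0.1), rep(0, d - 2))
  neg <- random_unit_cols(d, 5, rng) * 0.99 +
    matrix(rep(c(0.01, rep(0, d - 1)), 5), d, 5)
  neg <- sweep(neg, 2, sqrt(colSums(neg^2)), "/")
  stopifnot(max(crossprod(neg, q)) < sum(q * kpos))
  expect_lt(moco_infonce_loss(q, kpos, neg, tau = 1e-3), 1e-10)

  expect_error(moco_infonce_loss(q, q, matrix(numeric(0), d, 0), tau = 1),
               "empty")
})

test_that("queue InfoNCE equals batch NT-Xent under the {q, k+} + queue construction", {
  rng <- rng_new(25L)
  worst <- 0
  for (i in 1:200) {
    d <- 4L + (i %% 5L)
    K <- 2L + (i %% 17L)
    tau <- 0.05 + rng_runif(rng, 1) * 0.95
    q <- random_unit(d, rng)
    kpos <- random_unit(d, rng)
    queue <- random_unit_cols(d, K, rng)
    a <- moco_infonce_loss(q, kpos, queue, tau)
    b <- nt_xent_pair_loss(1, 2, rbind(q, kpos, t(queue)), tau)
    worst <- max(worst, abs(a - b))
  }
  expect_lt(worst, 1e-10)
})

test_that("the loss is invariant to the storage order of the negatives", {
  rng <- rng_new(35L)
  q <- random_unit(8, rng); kpos <- random_unit(8, rng)
  negs <- random_unit_cols(8, 12, rng)
  l1 <- moco_infonce_loss(q, kpos, negs, 0.07)
  l2 <- moco_infonce_loss(q, kpos, negs[, sample(12)], 0.07)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("analytic loss gradients match central finite differences", {
  rng <- rng_new(45L)
  for (rep_ in 1:10) {
    d <- 8L
    E <- matrix(rng_rnorm(rng, d * 3), d, 3)   # raw (unnormalised) queries
    Kpos <- random_unit_cols(d, 3, rng)
    negs <- random_unit_cols(d, 6, rng)
    tau <- 0.2
    loss_of <- function(Em) {
      nq <- equimoco:::.l2_normalize_cols(Em)
      equimoco:::.infonce_batch(nq$Q, Kpos, negs, tau)$loss
    }
    nq <- equimoco:::.l2_normalize_cols(E)
    lb <- equimoco:::.infonce_batch(nq$Q, Kpos, negs, tau)
    dE <- equimoco:::.l2_normalize_cols_backward(E, nq, lb$dQ)
    eps <- 1e-6
    for (t_ in seq_len(length(E))) {
      Ep <- E; Ep[t_] <- E[t_] + eps
      Em <- E; Em[t_] <- E[t_] - eps
      fd <- (loss_of(Ep) - loss_of(Em)) / (2 * eps)
      expect_equal(dE[t_], fd, tolerance = 1e-4)
    }
  }
})

test_that("the momentum update has its EMA fixed points", {
  qp <- list(list(W = matrix(1, 2, 2), b = c(1, 1)))
  kp <- list(list(W = matrix(0, 2, 2), b = c(0, 0)))
  expect_identical(momentum_update(qp, kp, m = 1), kp)
  expect_identical(momentum_update(qp, kp, m = 0), qp)
  upd <- momentum_update(qp, kp, m = 0.999)
  expect_equal(upd[[1]]$W[1, 1], 0.001, tolerance = 1e-15)
  bad <- list(list(W = matrix(0, 3, 2), b = c(0, 0)))
  expect_error(momentum_update(qp, bad, 0.5), "shapes")
  expect_error(momentum_update(qp, kp, 1.5), "m")
})

test_that("the key queue is FIFO and matches a brute-force oracle", {
  rng <- rng_new(55L)
  q <- queue_init(3, 4, init = "empty")
  a <- random_unit_cols(3, 2, rng); b <- random_unit_cols(3, 2, rng)
  c_ <- random_unit_cols(3, 2, rng)
  q <- enqueue(q, a)
  expect_identical(q$fill, 2L)
  q <- enqueue(q, b); q <- enqueue(q, c_)
  expect_identical(q$fill, 4L)
  # oldest batch evicted: contents are {b, c}
  got <- queue_keys(q)
  want <- cbind(b, c_)
  expect_identical(dim(got), dim(want))
  key_set <- function(m) apply(m, 2, paste, collapse = ",")
  expect_setequal(key_set(got), key_set(want))

  # randomized equivalence against a keep-last-K list oracle
  for (trial in 1:20) {
    K <- 3L + trial %% 5L
    qq <- queue_init(4, K, init = "empty")
    oracle <- matrix(numeric(0), 4, 0)
    for (step in 1:6) {
      B <- 1L + (trial + step) %% 4L
      keys <- random_unit_cols(4, B, rng)
      qq <- enqueue(qq, keys)
      oracle <- cbind(oracle, keys)
      if (ncol(oracle) > K) oracle <- oracle[, (ncol(oracle) - K + 1):ncol(oracle), drop = FALSE]
      expect_identical(qq$fill, ncol(oracle))
      expect_setequal(key_set(queue_keys(qq)), key_set(oracle))
    }
  }

  expect_error(enqueue(q, random_unit_cols(5, 1, rng)), "dimension")
  expect_error(enqueue(q, matrix(c(2, 0, 0), ncol = 1)), "unit-norm")
})

test_that("a warm-started queue is full of unit keys", {
  q <- queue_init(8, 32, init = "random", rng = rng_new(65L))
  expect_identical(q$fill, 32L)
  expect_true(all(abs(sqrt(colSums(queue_keys(q)^2)) - 1) < 1e-10))
})

test_that("pretraining runs, is finite, and is seed-deterministic", {
  ds <- cached("pretrain_smoke", {
    generate_posture_dataset(fixture_spec(n_classes = 2L, n_per_class = 8L,
                                          seed = 201L))
  })
  aug <- augment_config(size = 32L)
  enc <- encoder_config(input_size = 32L, representation_dim = 8L,
                        conv_channels = c(2L, 2L, 4L, 4L), fc_hidden = 16L,
                        dropout_p = 0.1, seed = 3L)
  con <- contrastive_config(queue_capacity = 16L, batch_size = 8L,
                            epochs = 3L, learning_rate = 0.01, seed = 7L)
  r1 <- pretrain(ds$images, aug, enc, con)
  expect_length(r1$record$loss_history, 3L)
  expect_true(all(is.finite(r1$record$loss_history)))
  r2 <- pretrain(ds$images, aug, enc, con)
  expect_identical(r1$record$loss_history, r2$record$loss_history)
  expect_identical(equimoco:::net_params(r1$encoder$net),
                   equimoco:::net_params(r2$encoder$net))
  expect_error(pretrain(list(), aug, enc, con), "empty")
})

test_that("m = 1 freezes the key encoder at its initial weights", {
  ds <- cached("pretrain_smoke", {
    generate_posture_dataset(fixture_spec(n_classes = 2L, n_per_class = 8L,
                                          seed = 201L))
  })
  aug <- augment_config(size = 32L)
  enc <- encoder_config(input_size = 32L, representation_dim = 8L,
                        conv_channels = c(2L, 2L, 4L, 4L), fc_hidden = 16L,
                        dropout_p = 0, seed = 3L)
  con <- contrastive_config(momentum = 1, queue_capacity = 16L,
                            batch_size = 8L, epochs = 2L,
                            learning_rate = 0.01, seed = 7L)
  r <- pretrain(ds$images, aug, enc, con)
  init <- build_encoder(enc)
  expect_identical(equimoco:::net_params(r$key_encoder$net),
                   equimoco:::net_params(init$net))
  # ... while the query encoder did move
  expect_false(identical(equimoco:::net_params(r$encoder$net),
                         equimoco:::net_params(init$net)))
})

test_that("contrastive configuration validation", {
  expect_error(contrastive_config(temperature = 0), "temperature")
  expect_error(contrastive_config(momentum = 1.2), "momentum")
  expect_error(contrastive_config(queue_capacity = 8, batch_size = 32),
               "queue_capacity")
})
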