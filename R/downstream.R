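# Frozen-encoder downstream classification.
#
# The pretrained encoder is frozen and used purely as a feature extractor;
# a small fully connected head (64 -> 256 -> 128 -> 64 -> n_classes, batch
# normalisation + ReLU + dropout 0.5/0.5/0.3 between stages) is trained with
# cross-entropy on the labeled fine-tuning split.  Because the encoder never
# receives gradients, its features are computed once per image and the head
# trains on cached embeddings.

#' Downstream head configuration
#'
#' @param feature_dim Encoder representation dimension (must match).
#' @param hidden_dims Widths of the three hidden stages.
#' @param dropouts Dropout probabilities after each hidden stage.
#' @param n_classes Number of emotion classes.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (>= 2: batch normalisation needs more
#'   than one sample in training mode).
#' @param learning_rate,optimizer_momentum,weight_decay SGD parameters
#'   (defaults mirror the pretraining optimizer).
#' @param val_fraction Fraction of the fine-tuning set held out as an
#'   internal validation set for the accuracy curve.
#' @param seed Seed for shuffling, dropout and weight initialisation.
#' @return A `head_config` object.
#' @export
head_config <- function(feature_dim = 64L, hidden_dims = c(256L, 128L, 64L),
                        dropouts = c(0.5, 0.5, 0.3), n_classes = 8L,
                        epochs = 500L, batch_size = 32L,
                        learning_rate = 1e-4, optimizer_momentum = 0.9,
                        weight_decay = 1e-4, val_fraction = 0.2, seed = 1L) {
  stopifnot(length(hidden_dims) == 3L, length(dropouts) == 3L,
            all(dropouts >= 0), all(dropouts < 1), n_classes >= 2,
            batch_size >= 2, epochs >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(feature_dim = as.integer(feature_dim),
                 hidden_dims = as.integer(hidden_dims),
                 dropouts = dropouts, n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer_momentum = optimizer_momentum,
                 weight_decay = weight_decay,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "head_config")
}

#' Parameter count of the head as a pure function of its configuration
#'
#' Linear layers plus two scalars (scale and shift) per batch-normalised
#' feature.
#'
#' @param config A [head_config()].
#' @export
head_param_count <- function(config) {
  dims <- c(config$feature_dim, config$hidden_dims, config$n_classes)
  lin <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  bn <- 2 * sum(config$hidden_dims)
  lin + bn
}

#' Attach a classification head to a frozen encoder
#'
#' The encoder's parameters are excluded from every gradient update the head
#' ever takes; [train_head()] additionally verifies bit-identity of the
#' encoder before and after training.
#'
#' @param encoder A trained `posture_encoder`.
#' @param config A [head_config()]; `feature_dim` must equal the encoder's
#'   representation dimension.
#' @param augment_cfg The [augment_config()] whose deterministic
#'   [eval_transform()] prepares images for the encoder.
#' @return A `posture_classifier`.
#' @export
build_head <- function(encoder, config = head_config(),
                       augment_cfg = NULL) {
  stopifnot(inherits(encoder, "posture_encoder"),
            inherits(config, "head_config"))
  if (config$feature_dim != encoder$config$representation_dim) {
    stop("head feature_dim (", config$feature_dim,
         ") does not match the encoder representation dimension (",
         encoder$config$representation_dim, ")", call. = FALSE)
  }
  if (is.null(augment_cfg)) {
    augment_cfg <- augment_config(size = encoder$config$input_size)
  }
  rng <- rng_new(config$seed)
  h <- config$hidden_dims
  layers <- list(
    layer_linear(config$feature_dim, h[1], rng), layer_batchnorm(h[1]),
    layer_relu(), layer_dropout(config$dropouts[1]),
    layer_linear(h[1], h[2], rng), layer_batchnorm(h[2]),
    layer_relu(), layer_dropout(config$dropouts[2]),
    layer_linear(h[2], h[3], rng), layer_batchnorm(h[3]),
    layer_relu(), layer_dropout(config$dropouts[3]),
    layer_linear(h[3], config$n_classes, rng)
  )
  structure(list(encoder = encoder, head = list(layers = layers),
                 config = config, augment_cfg = augment_cfg,
                 classes = emotion_levels()[seq_len(config$n_classes)]),
            class = "posture_classifier")
}

# encode raw images through the frozen encoder (deterministic eval views)
classifier_features <- function(classifier, images) {
  views <- lapply(images, eval_transform, config = classifier$augment_cfg)
  t(encode(classifier$encoder, views, normalize = TRUE))  # (d, N)
}

.softmax_ce <- function(logits, y) {
  # logits (C, N); y integer class indices 1..C
  N <- ncol(logits)
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx, "-"))
  p <- sweep(ex, 2, colSums(ex), "/")
  picked <- p[cbind(y, seq_len(N))]
  loss <- mean(-log(pmax(picked, 1e-300)))
  dlogits <- p
  dlogits[cbind(y, seq_len(N))] <- dlogits[cbind(y, seq_len(N))] - 1
  list(loss = loss, dlogits = dlogits / N)
}

.head_predict <- function(classifier, feats) {
  logits <- net_forward(classifier$head, feats, train = FALSE)$out
  # ties broken toward the lowest class index
  max.col(t(logits), ties.method = "first")
}

#' Train the classification head on labeled features
#'
#' Cross-entropy training of the head with the encoder frozen.  An internal
#' validation split (`val_fraction` of the data, seeded) tracks per-epoch
#' train/validation accuracy.
#'
#' @param classifier A `posture_classifier` from [build_head()].
#' @param images List of grayscale image matrices.
#' @param labels Character emotion labels, one per image; `NA` labels are
#'   refused.
#' @param epochs Optional override of the configured epoch count.
#' @return List with the trained `classifier` and `history` (data.frame
#'   `epoch, loss, train_accuracy, val_accuracy`).
#' @export
train_head <- function(classifier, images, labels, epochs = NULL) {
  stopifnot(inherits(classifier, "posture_classifier"))
  cfg <- classifier$config
  if (length(images) != length(labels)) {
    stop("`images` and `labels` lengths differ", call. = FALSE)
  }
  if (anyNA(labels)) {
    stop("unlabeled row in the fine-tuning split (row ",
         which(is.na(labels))[1L], "): labels are required for training",
         call. = FALSE)
  }
  bad <- !(labels %in% classifier$classes)
  if (any(bad)) {
    stop("label \"", labels[which(bad)[1L]], "\" at row ", which(bad)[1L],
         " is outside the classifier's taxonomy", call. = FALSE)
  }
  if (is.null(epochs)) epochs <- cfg$epochs
  encoder_before <- net_params(classifier$encoder$net)

  y <- match(labels, classifier$classes)
  feats <- classifier_features(classifier, images)  # (d, N)
  n <- ncol(feats)
  rng <- rng_new(cfg$seed)
  n_val <- floor(cfg$val_fraction * n)
  val_idx <- if (n_val > 0) rng_sample(rng, n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) < 2L) {
    stop("need at least 2 training samples (batch normalisation)",
         call. = FALSE)
  }
  head <- classifier$head
  opt_state <- sgd_state_init(head)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_accuracy = numeric(0), val_accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- rng_sample(rng, tr_idx)
    losses <- c()
    b0 <- 1L
    while (b0 <= length(ord)) {
      b1 <- min(b0 + cfg$batch_size - 1L, length(ord))
      idx <- ord[b0:b1]
      b0 <- b1 + 1L
      if (length(idx) < 2L) next  # batch norm needs > 1 sample
      f <- net_forward(head, feats[, idx, drop = FALSE], train = TRUE,
                       rng = rng)
      head <- f$net
      ce <- .softmax_ce(f$out, y[idx])
      losses <- c(losses, ce$loss)
      grads <- net_backward(head, f$caches, ce$dlogits)$grads
      st <- sgd_step(head, grads, opt_state, cfg$learning_rate,
                     cfg$optimizer_momentum, cfg$weight_decay)
      head <- st$net
      opt_state <- st$state
    }
    cl_tmp <- classifier; cl_tmp$head <- head
    pred_tr <- .head_predict(cl_tmp, feats[, tr_idx, drop = FALSE])
    acc_tr <- mean(pred_tr == y[tr_idx])
    acc_val <- if (length(val_idx) > 0) {
      mean(.head_predict(cl_tmp, feats[, val_idx, drop = FALSE]) == y[val_idx])
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   train_accuracy = acc_tr,
                                   val_accuracy = acc_val))
  }
  classifier$head <- head
  if (!identical(encoder_before, net_params(classifier$encoder$net))) {
    stop("internal error: encoder parameters changed during head training")
  }
  list(classifier = classifier, history = hist)
}

#' Predict emotion labels for images
#'
#' @param classifier A trained `posture_classifier`.
#' @param images List of grayscale image matrices.
#' @return Character vector of predicted labels.
#' @export
predict_classifier <- function(classifier, images) {
  feats <- classifier_features(classifier, images)
  classifier$classes[.head_predict(classifier, feats)]
}

#' Evaluate a classifier on a labeled test set
#'
#' @param classifier A trained `posture_classifier`.
#' @param images List of grayscale image matrices (non-empty).
#' @param labels Character emotion labels, one per image.
#' @return A `classification_report`: `overall_accuracy` (fraction),
#'   `per_class_accuracy` (named; `NA` for classes absent from the test
#'   set), `confusion_matrix` (true classes in rows), `n_evaluated`.
#' @export
evaluate <- function(classifier, images, labels) {
  if (length(images) == 0L) stop("empty test set", call. = FALSE)
  if (anyNA(labels)) stop("test labels must be complete", call. = FALSE)
  pred <- predict_classifier(classifier, images)
  classes <- classifier$classes
  cm <- table(factor(labels, levels = classes),
              factor(pred, levels = classes))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(truth = classes, predicted = classes))
  support <- rowSums(cm)
  per_class <- ifelse(support > 0, diag(cm) / support, NA_real_)
  names(per_class) <- classes
  structure(list(overall_accuracy = sum(diag(cm)) / sum(cm),
                 per_class_accuracy = per_class,
                 confusion_matrix = cm,
                 n_evaluated = sum(cm)),
            class = "classification_report")
}

#' Expected accuracy of a uniform random guesser
#'
#' The analytic downstream baseline: guessing uniformly over `n_classes`
#' yields expected accuracy `1 / n_classes` on any test set (12.5% for the
#' eight-emotion taxonomy).  With `n_draws` set, the value is instead
#' estimated by Monte-Carlo simulation of a uniform guesser.
#'
#' @param n_classes Number of classes.
#' @param n_draws Optional number of Monte-Carlo draws.
#' @param rng Generator used for the simulation.
#' @return Expected accuracy as a fraction.
#' @export
random_baseline_accuracy <- function(n_classes = 8L, n_draws = NULL,
                                     rng = rng_new(0L)) {
  stopifnot(n_classes >= 1)
  if (is.null(n_draws)) return(1 / n_classes)
  truth <- rng_sample(rng, n_classes, n_draws, replace = TRUE)
  guess <- rng_sample(rng, n_classes, n_draws, replace = TRUE)
  mean(truth == guess)
}
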