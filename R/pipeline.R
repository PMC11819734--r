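# Desk-scale study: the full pipeline (fixtures -> split -> contrastive
# pretraining -> embedding analysis -> frozen-encoder head -> evaluation)
# at a problem size that runs in minutes on one CPU core.
#
# The published training configuration (112-pixel inputs, 65,536-key queue,
# 2000 epochs, the full 32/64/128/256 channel ladder) targets GPU hardware
# and a 3,374-image corpus; the desk profile keeps every mechanism identical
# but shrinks the problem: 32-pixel fixtures, 8 classes x 32 images, a
# narrower 8/16/32/32 ladder with a 128-unit hidden layer, dropout 0.2, a
# 128-key queue grown from real keys, and a few dozen epochs.  The SGD step
# (0.05) and key momentum (0.99) are larger than the full-scale values
# because a 400-step budget must both escape the near-collapsed
# initialisation (a deep ReLU stack starts with all embeddings almost
# parallel) and let the key encoder track the query encoder within the run.

#' Desk-scale configuration profile
#'
#' Returns matched fixture/augment/encoder/contrastive/head configurations
#' for a scaled-down end-to-end run.
#'
#' @param seed Master seed; sub-seeds are derived from it.
#' @param n_per_class Fixture images per class.
#' @param image_size Fixture and encoder input side in pixels.
#' @param epochs Pretraining epochs.
#' @param queue_capacity Key-queue size.
#' @return Named list of configuration objects.
#' @export
desk_profile <- function(seed = 1L, n_per_class = 32L, image_size = 32L,
                         epochs = 50L, queue_capacity = 128L) {
  master <- rng_new(seed)
  s_fix <- rng_child_seed(master)
  s_enc <- rng_child_seed(master)
  s_con <- rng_child_seed(master)
  s_head <- rng_child_seed(master)
  s_split <- rng_child_seed(master)
  list(
    fixture = fixture_spec(n_classes = 8L, n_per_class = n_per_class,
                           image_size = image_size, noise_sd = 0.02,
                           seed = s_fix),
    augment = augment_config(size = image_size),
    encoder = encoder_config(input_size = image_size,
                             representation_dim = 64L,
                             conv_channels = c(8L, 16L, 32L, 32L),
                             fc_hidden = 128L, dropout_p = 0.2,
                             seed = s_enc),
    contrastive = contrastive_config(queue_capacity = queue_capacity,
                                     batch_size = 32L, epochs = epochs,
                                     learning_rate = 0.05, momentum = 0.99,
                                     queue_init = "empty", seed = s_con),
    head = head_config(epochs = 150L, learning_rate = 5e-2,
                       batch_size = 16L, seed = s_head),
    split_seed = s_split
  )
}

#' Run the full pipeline at desk scale
#'
#' Generates the default 8-class fixture set, splits it 50/25/25 into
#' pretraining / fine-tuning / held-out test partitions (stratified by
#' breed), pretrains the encoder with momentum contrast, compares the
#' silhouette of the latent classes in trained vs untrained embedding
#' space, trains the frozen-encoder head, and evaluates on the held-out
#' fixtures.
#'
#' @param seed Master seed.
#' @param ... Passed to [desk_profile()].
#' @return List with `loss_history`, `silhouette_untrained`,
#'   `silhouette_trained`, `report` (test-set `classification_report`),
#'   `head_history`, `profile`, and `separability` (the raw-pixel fixture
#'   oracle accuracy).
#' @export
run_desk_study <- function(seed = 1L, ...) {
  prof <- desk_profile(seed, ...)
  ds <- generate_posture_dataset(prof$fixture)
  sp <- stratified_split(ds$manifest, fractions = c(0.5, 0.25, 0.25),
                         seed = prof$split_seed)
  man <- sp$manifest
  part <- function(which_) which(man$split == which_)
  img <- ds$images
  sep <- fixture_separability_check(img, man)

  # corpus-level normalisation constants, fitted once on the pretraining
  # split and stored in the run configuration
  nz <- estimate_normalization(img[part("pretrain")], prof$augment)
  prof$augment$normalize_mean <- nz[["mean"]]
  prof$augment$normalize_sd <- nz[["sd"]]

  pre <- pretrain(img[part("pretrain")], prof$augment, prof$encoder,
                  prof$contrastive)

  views <- lapply(img[part("pretrain")], eval_transform,
                  config = prof$augment)
  labs <- man$emotion[part("pretrain")]
  enc0 <- build_encoder(prof$encoder)
  sil0 <- embedding_silhouette(encode(enc0, views), labs)
  sil1 <- embedding_silhouette(encode(pre$encoder, views), labs)

  clf <- build_head(pre$encoder, prof$head, prof$augment)
  tr <- train_head(clf, img[part("finetune")], man$emotion[part("finetune")])
  rep_ <- evaluate(tr$classifier, img[part("test")], man$emotion[part("test")])

  list(loss_history = pre$record$loss_history,
       silhouette_untrained = sil0, silhouette_trained = sil1,
       report = rep_, head_history = tr$history,
       profile = prof, separability = sep)
}
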