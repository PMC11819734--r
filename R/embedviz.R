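# Embedding-space analysis: t-SNE projection for display, silhouette-scored
# k-means for an auditable cluster count, and labeled scatter plots.
#
# Cluster counting runs on the full-dimensional embeddings, not the 2-D
# projection: t-SNE distorts densities, so the 2-D view is display only.

#' Project embeddings to 2-D with t-SNE
#'
#' @param embeddings `n x d` numeric matrix (`n > 3 * perplexity + 1`).
#' @param perplexity t-SNE perplexity (effective neighbourhood size;
#'   default 30).
#' @param seed Seed making the projection reproducible.
#' @param max_iter Optimisation iterations.
#' @return `n x 2` coordinate matrix.
#' @export
project_embeddings <- function(embeddings, perplexity = 30, seed = 1L,
                               max_iter = 1000L) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n <= 3 * perplexity + 1) {
    stop("too few points (", n, ") for perplexity ", perplexity,
         "; need n > 3 * perplexity + 1 — use a smaller perplexity",
         call. = FALSE)
  }
  stopifnot(ncol(embeddings) >= 2)
  fit <- rng_eval(rng_new(seed),
                  Rtsne::Rtsne(embeddings, dims = 2, perplexity = perplexity,
                               max_iter = max_iter, pca = FALSE,
                               check_duplicates = FALSE, verbose = FALSE))
  fit$Y
}

#' Estimate the number of clusters in embedding space
#'
#' Runs k-means (multiple restarts, fixed seed) for every k in `k_range` and
#' scores each clustering by the mean silhouette width; the estimate is the
#' argmax, and the full score table is returned so claims about cluster
#' counts are auditable.
#'
#' @param embeddings `n x d` numeric matrix.
#' @param k_range Candidate cluster counts (subset of 2..n/2).
#' @param seed Seed for the k-means restarts.
#' @param nstart Restarts per k.
#' @return A `cluster_estimate`: `k_best`, `score_by_k` (named numeric),
#'   `method`.
#' @export
estimate_cluster_count <- function(embeddings, k_range = 2:12, seed = 1L,
                                   nstart = 10L) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n / 2)) {
    stop("`k_range` must lie within [2, n/2]", call. = FALSE)
  }
  if (n < 2L * max(k_range)) {
    stop("need at least 2 * max(k_range) points", call. = FALSE)
  }
  if (all(apply(embeddings, 2, function(col) length(unique(col)) == 1L))) {
    stop("degenerate embeddings: all points identical", call. = FALSE)
  }
  D <- stats::dist(embeddings)
  rng <- rng_new(seed)
  scores <- vapply(k_range, function(k) {
    cl <- rng_eval(rng, stats::kmeans(embeddings, centers = k,
                                      nstart = nstart, iter.max = 100L))
    sil <- cluster::silhouette(cl$cluster, D)
    mean(sil[, 3])
  }, numeric(1))
  names(scores) <- k_range
  structure(list(k_best = k_range[which.max(scores)],
                 score_by_k = scores,
                 method = "kmeans-silhouette"),
            class = "cluster_estimate")
}

#' Mean silhouette width of embeddings under known labels
#'
#' Scores how well a labelling (e.g. the latent fixture classes) is
#' separated in embedding space — the computable version of "the trained
#' encoder clusters the data better than the untrained one".
#'
#' @param embeddings `n x d` numeric matrix.
#' @param labels Vector of group labels (>= 2 distinct values).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
embedding_silhouette <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  stopifnot(nrow(embeddings) == length(labels))
  f <- as.integer(factor(labels))
  if (length(unique(f)) < 2L) {
    stop("need >= 2 distinct labels for a silhouette score", call. = FALSE)
  }
  sil <- cluster::silhouette(f, stats::dist(embeddings))
  mean(sil[, 3])
}

#' Scatter plot of 2-D embedding coordinates
#'
#' One colour per label with a legend, or a single colour in unlabeled mode.
#'
#' @param coords `n x 2` coordinate matrix (n >= 1).
#' @param labels Optional label vector of length n.
#' @param path Output file (PNG).
#' @param title Plot title.
#' @return The path, invisibly.
#' @export
plot_embedding <- function(coords, labels = NULL, path, title = "Embedding") {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("empty coordinates", call. = FALSE)
  stopifnot(ncol(coords) == 2L)
  if (!is.null(labels) && length(labels) != nrow(coords)) {
    stop("`labels` length (", length(labels),
         ") does not match the number of points (", nrow(coords), ")",
         call. = FALSE)
  }
  df <- data.frame(x = coords[, 1], y = coords[, 2])
  if (is.null(labels)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
      ggplot2::geom_point(colour = "grey30", size = 1)
  } else {
    df$label <- as.factor(labels)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = label)) +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(colour = "label")
  }
  p <- p + ggplot2::labs(title = title, x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 5, dpi = 120)
  invisible(path)
}
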