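# Asymmetric query/key augmentation pipelines for contrastive training.
#
# Both branches share: random resized crop -> grayscale -> Sobel edge
# magnitude -> normalisation, and always emit exactly one channel (that is
# what licenses the single-channel encoder).  Only the query branch adds the
# stochastic horizontal flip (p = 0.5) and occasional Gaussian blur
# (p = 0.1), and it crops more aggressively (area scale 0.66..1 vs 0.85..1),
# so the key view remains a more deterministic, context-preserving baseline.

#' Augmentation configuration
#'
#' @param size Output side in pixels.
#' @param query_crop_scale,key_crop_scale Area-fraction intervals for the
#'   random resized crop of each branch.
#' @param flip_prob Horizontal-flip probability (query branch only).
#' @param blur_prob Gaussian-blur probability (query branch only).
#' @param blur_kernel Odd blur kernel side in pixels.
#' @param blur_sigma_range Blur sigma is drawn uniformly from this interval
#'   (pixels).
#' @param aspect_range Aspect-ratio interval for the random resized crop.
#' @param normalize_mean,normalize_sd Post-Sobel normalisation constants
#'   (identity by default; fit corpus-level constants with
#'   [estimate_normalization()]).
#' @return An `augment_config` object.
#' @export
augment_config <- function(size = 112L,
                           query_crop_scale = c(0.66, 1.0),
                           key_crop_scale = c(0.85, 1.0),
                           flip_prob = 0.5,
                           blur_prob = 0.1,
                           blur_kernel = 5L,
                           blur_sigma_range = c(0.1, 2.0),
                           aspect_range = c(3 / 4, 4 / 3),
                           normalize_mean = 0,
                           normalize_sd = 1) {
  for (iv in list(query_crop_scale, key_crop_scale)) {
    if (length(iv) != 2L || iv[1] <= 0 || iv[1] > iv[2] || iv[2] > 1) {
      stop("crop scale intervals must satisfy 0 < lower <= upper <= 1",
           call. = FALSE)
    }
  }
  for (p in c(flip_prob, blur_prob)) {
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  stopifnot(size >= 4, blur_kernel %% 2 == 1, normalize_sd > 0)
  structure(list(size = as.integer(size),
                 query_crop_scale = query_crop_scale,
                 key_crop_scale = key_crop_scale,
                 flip_prob = flip_prob, blur_prob = blur_prob,
                 blur_kernel = as.integer(blur_kernel),
                 blur_sigma_range = blur_sigma_range,
                 aspect_range = aspect_range,
                 normalize_mean = normalize_mean,
                 normalize_sd = normalize_sd),
            class = "augment_config")
}

#' Sobel edge-magnitude filter
#'
#' Gradient magnitude `sqrt(Gx^2 + Gy^2)` from the standard 3x3 Sobel kernel
#' pair with reflective border handling.  The posture contour is the signal
#' the pipeline cares about; the Sobel magnitude accentuates it while
#' discarding flat colour/terrain information.  By default the output is
#' rescaled to \[0, 1\] by the theoretical maximum response `4 * sqrt(2)`
#' (each kernel's response to \[0,1\] inputs is bounded by 4 in absolute
#' value).
#'
#' @param image Single-channel matrix, at least 3x3.
#' @param rescale Divide by the theoretical maximum response (default TRUE).
#' @return Matrix of the same shape.
#' @export
sobel_filter <- function(image, rescale = TRUE) {
  if (!is.matrix(image)) image <- to_grayscale(image)
  if (nrow(image) < 3L || ncol(image) < 3L) {
    stop("image must be at least 3x3 for the Sobel kernels", call. = FALSE)
  }
  # row index = image row (y), so the "horizontal" gradient Gx differentiates
  # across columns and Gy across rows
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- conv2_reflect(image, kx)
  gy <- conv2_reflect(image, ky)
  mag <- sqrt(gx^2 + gy^2)
  if (rescale) mag <- mag / (4 * sqrt(2))
  mag
}

# Sample a crop rectangle with area fraction in `scale` and aspect ratio
# log-uniform in `ratio` (the standard random-resized-crop algorithm with a
# centre-crop fallback), then resize to size x size bilinearly.
random_resized_crop <- function(image, size, scale, ratio, rng) {
  h <- nrow(image); w <- ncol(image)
  area <- h * w
  for (i in 1:10) {
    target_area <- rng_runif(rng, 1, scale[1], scale[2]) * area
    log_ratio <- rng_runif(rng, 1, log(ratio[1]), log(ratio[2]))
    ar <- exp(log_ratio)
    # ceiling keeps the realised area at or above the drawn fraction even on
    # coarse pixel grids
    cw <- as.integer(ceiling(sqrt(target_area * ar)))
    ch <- as.integer(ceiling(sqrt(target_area / ar)))
    if (cw >= 3L && ch >= 3L && cw <= w && ch <= h) {
      x0 <- as.integer(floor(rng_runif(rng, 1, 0, w - cw + 1)))
      y0 <- as.integer(floor(rng_runif(rng, 1, 0, h - ch + 1)))
      x0 <- min(x0, w - cw); y0 <- min(y0, h - ch)
      crop <- image[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), drop = FALSE]
      attr_area <- (cw * ch) / area
      out <- bilinear_resize(crop, size, size)
      attr(out, "crop_area_fraction") <- attr_area
      return(out)
    }
  }
  # fallback: largest centre crop at the mean requested aspect
  ch <- min(h, w); cw <- ch
  if (cw < 3L || ch < 3L) {
    stop("source image too small to crop (needs >= 3x3)", call. = FALSE)
  }
  y0 <- (h - ch) %/% 2L; x0 <- (w - cw) %/% 2L
  crop <- image[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), drop = FALSE]
  out <- bilinear_resize(crop, size, size)
  attr(out, "crop_area_fraction") <- (cw * ch) / area
  out
}

.normalize_view <- function(x, config) {
  (x - config$normalize_mean) / config$normalize_sd
}

#' Query-branch augmentation
#'
#' Applies, in order: random resized crop (area scale from
#' `query_crop_scale`), grayscale conversion, horizontal flip with
#' probability `flip_prob`, Gaussian blur with probability `blur_prob`,
#' the Sobel filter, and normalisation.  All randomness comes from the
#' supplied generator.
#'
#' @param image Matrix or RGB array.
#' @param config An [augment_config()].
#' @param rng An [rng_new()] generator.
#' @return `size` x `size` single-channel matrix.
#' @export
query_transform <- function(image, config, rng) {
  g <- to_grayscale(image)
  v <- random_resized_crop(g, config$size, config$query_crop_scale,
                           config$aspect_range, rng)
  attr(v, "crop_area_fraction") <- NULL
  if (rng_runif(rng, 1) < config$flip_prob) {
    v <- v[, rev(seq_len(ncol(v))), drop = FALSE]
  }
  if (rng_runif(rng, 1) < config$blur_prob) {
    sigma <- rng_runif(rng, 1, config$blur_sigma_range[1],
                       config$blur_sigma_range[2])
    v <- gaussian_blur(v, config$blur_kernel, sigma)
  }
  .normalize_view(sobel_filter(v), config)
}

#' Key-branch augmentation
#'
#' As [query_transform()] but with the tighter `key_crop_scale` and
#' deliberately without flips or blur.
#'
#' @inheritParams query_transform
#' @return `size` x `size` single-channel matrix.
#' @export
key_transform <- function(image, config, rng) {
  g <- to_grayscale(image)
  v <- random_resized_crop(g, config$size, config$key_crop_scale,
                           config$aspect_range, rng)
  af <- attr(v, "crop_area_fraction")
  attr(v, "crop_area_fraction") <- NULL
  out <- .normalize_view(sobel_filter(v), config)
  attr(out, "crop_area_fraction") <- af
  out
}

#' Deterministic evaluation transform
#'
#' Full-frame resize, grayscale, Sobel, normalisation — no randomness.  Used
#' when encoding images for downstream classification or embedding analysis.
#'
#' @inheritParams query_transform
#' @export
eval_transform <- function(image, config) {
  g <- bilinear_resize(to_grayscale(image), config$size, config$size)
  .normalize_view(sobel_filter(g), config)
}

#' Paired query/key views of one image
#'
#' Independent draws of the query and key branches from the same source
#' image — the two-crops construction contrastive training consumes.
#'
#' @inheritParams query_transform
#' @return A `view_pair`: list with single-channel matrices `query_view`
#'   and `key_view`.
#' @export
two_crops <- function(image, config, rng) {
  q <- query_transform(image, config, rng)
  k <- key_transform(image, config, rng)
  attr(k, "crop_area_fraction") <- NULL
  structure(list(query_view = q, key_view = k), class = "view_pair")
}

#' Fit corpus-level normalisation constants
#'
#' Computes the mean and standard deviation of Sobel views of a set of
#' images, for use as `normalize_mean` / `normalize_sd` in the run
#' configuration.
#'
#' @param images List of image matrices.
#' @param config An [augment_config()].
#' @return Named numeric vector `c(mean, sd)`.
#' @export
estimate_normalization <- function(images, config) {
  vals <- unlist(lapply(images, function(im) {
    as.vector(sobel_filter(bilinear_resize(to_grayscale(im),
                                           config$size, config$size)))
  }))
  c(mean = mean(vals), sd = stats::sd(vals))
}
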