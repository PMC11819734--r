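# Synthetic posture fixtures.
#
# The pipeline was designed for photographs of wild horses in which body
# posture (neck, head and tail carriage) carries the affective signal.  That
# corpus is proprietary, so the package ships a generator of grayscale
# silhouette images whose latent class is encoded purely in posture-like
# geometry: each of the eight emotion classes owns a distinct, non-overlapping
# region of (neck angle, head drop, tail angle) space, and intra-class
# variability comes from small angle/position jitter plus pixel noise.
# Classes differ only in geometry, never in texture.

#' The eight-emotion taxonomy
#'
#' Seven cross-mammalian primal affective systems (Care, Seeking, Fear, Lust,
#' Play, Rage, Grief) plus Pain, which is treated as an eighth category for
#' horses.  This fixed order is used everywhere labels are encoded.
#'
#' @return Character vector of length 8.
#' @export
emotion_levels <- function() {
  c("Care", "Fear", "Grief", "Lust", "Pain", "Play", "Rage", "Seeking")
}

# Aliases accepted on manifest read and normalised to the canonical names.
emotion_aliases <- function() {
  c(Affectionate = "Care", Exploring = "Seeking", Sadness = "Grief",
    Playing = "Play")
}

#' Reference per-breed image counts
#'
#' The per-breed counts of the five wild-horse populations the pipeline was
#' built around (Eriskay Pony, Insh Konik Pony, Pottoka, Skyros Pony, Konik);
#' they sum to 3,929 and are the default `breed_preset` for full-size
#' bookkeeping checks.
#'
#' @return Named integer vector summing to 3929.
#' @export
wild_horse_breed_counts <- function() {
  c(Eriskay = 711L, InshKonik = 781L, Pottoka = 809L,
    Skyros = 796L, Konik = 832L)
}

# Latent class -> posture geometry.  Angles in degrees: neck_angle above the
# horizontal, head_drop below the neck axis, tail_angle above the
# horizontal-backward direction.  The class/emotion pairing is arbitrary but
# fixed; fixtures test mechanics, not ethology.  Classes are separated by at
# least 10 degrees in some coordinate, so the +/-4 degree jitter never makes
# regions overlap.
posture_class_table <- function() {
  data.frame(
    emotion    = emotion_levels(),
    neck_angle = c(35, 75, -10, 55, -30, 65, 15,  5),
    head_drop  = c(10, -5,  55,  5,  70, -35, -15, 35),
    tail_angle = c(-30, 40, -70, 70, -10, 10,  55, -5),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic posture dataset
#'
#' @param n_classes Number of latent posture classes (1..8; each maps to one
#'   emotion name).
#' @param n_per_class Images per class (ignored when `breed_preset` is given).
#' @param image_size Pixels per side (>= 32).
#' @param breed_preset Optional named integer vector breed -> count; when
#'   given, the dataset has `sum(breed_preset)` rows and breeds are assigned
#'   in blocks.
#' @param noise_sd Additive Gaussian pixel noise, in \[0, 1\] intensity units.
#' @param blur_prob Probability that a fixture is pre-blurred.
#' @param seed Integer seed; identical specs (including seed) regenerate
#'   byte-identical output.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_classes = 8L, n_per_class = 16L, image_size = 32L,
                         breed_preset = NULL, noise_sd = 0.02,
                         blur_prob = 0, seed = 1L) {
  n_classes <- as.integer(n_classes)
  n_per_class <- as.integer(n_per_class)
  image_size <- as.integer(image_size)
  if (is.na(n_classes) || n_classes < 1L) {
    stop("invalid `n_classes`: must be >= 1", call. = FALSE)
  }
  if (n_classes > 8L) {
    stop("invalid `n_classes`: at most 8 (the emotion taxonomy size)",
         call. = FALSE)
  }
  if (is.na(n_per_class) || n_per_class < 0L) {
    stop("invalid `n_per_class`: must be >= 0", call. = FALSE)
  }
  if (is.na(image_size) || image_size < 32L) {
    stop("invalid `image_size`: must be >= 32", call. = FALSE)
  }
  if (!is.null(breed_preset)) {
    if (is.null(names(breed_preset)) || any(!nzchar(names(breed_preset)))) {
      stop("invalid `breed_preset`: must be a named count vector", call. = FALSE)
    }
    if (any(breed_preset < 0) || any(breed_preset != round(breed_preset))) {
      stop("invalid `breed_preset`: counts must be non-negative integers",
           call. = FALSE)
    }
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("invalid `noise_sd`: must be >= 0", call. = FALSE)
  }
  if (!is.numeric(blur_prob) || blur_prob < 0 || blur_prob > 1) {
    stop("invalid `blur_prob`: must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_classes = n_classes, n_per_class = n_per_class,
         image_size = image_size, breed_preset = breed_preset,
         noise_sd = noise_sd, blur_prob = blur_prob,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Posture parameters for one silhouette
#'
#' @param emotion One of [emotion_levels()].
#' @param jitter Numeric vector of 3 angle offsets in degrees added to the
#'   class base (neck, head, tail); kept within +/-4 degrees by the generator.
#' @param body_aspect Body length/height ratio multiplier.
#' @param leg_spread Leg separation multiplier.
#' @param scale Overall silhouette size as a fraction of the frame (<= 0.8
#'   guarantees the rendering stays fully inside the frame).
#' @param position Numeric (dx, dy) centre offset in frame fractions.
#' @return A list of class `silhouette_params`.
#' @export
silhouette_params <- function(emotion, jitter = c(0, 0, 0), body_aspect = 1,
                              leg_spread = 1, scale = 0.7,
                              position = c(0, 0)) {
  tab <- posture_class_table()
  row <- tab[tab$emotion == emotion, ]
  if (nrow(row) != 1L) {
    stop("unknown emotion class: ", emotion, call. = FALSE)
  }
  structure(
    list(emotion = emotion,
         body_aspect = body_aspect,
         neck_angle = row$neck_angle + jitter[1L],
         head_drop = row$head_drop + jitter[2L],
         tail_angle = row$tail_angle + jitter[3L],
         leg_spread = leg_spread,
         scale = scale,
         position = position),
    class = "silhouette_params"
  )
}

# --- rasterisation ----------------------------------------------------------

.in_ellipse <- function(px, py, cx, cy, a, b, theta = 0) {
  ct <- cos(theta); st <- sin(theta)
  u <- (px - cx) * ct + (py - cy) * st
  v <- -(px - cx) * st + (py - cy) * ct
  (u / a)^2 + (v / b)^2 <= 1
}

# convex quadrilateral given as 4 x 2 matrix of vertices in order
.in_quad <- function(px, py, v) {
  inside <- rep(TRUE, length(px))
  for (i in 1:4) {
    j <- if (i == 4) 1L else i + 1L
    cr <- (v[j, 1] - v[i, 1]) * (py - v[i, 2]) -
      (v[j, 2] - v[i, 2]) * (px - v[i, 1])
    inside <- inside & (cr <= 0)
  }
  inside
}

.quad_strip <- function(p0, p1, w0, w1) {
  d <- p1 - p0
  n <- c(-d[2], d[1]) / sqrt(sum(d^2))
  rbind(p0 + n * w0 / 2, p1 + n * w1 / 2, p1 - n * w1 / 2, p0 - n * w0 / 2)
}

# Render one silhouette; returns list(mask = logical matrix, fg/bg values are
# applied by the caller).  Row 1 is the top of the image; internal geometry
# uses y-up unit coordinates.
render_silhouette_mask <- function(params, image_size) {
  S <- as.integer(image_size)
  grid_c <- (seq_len(S) - 0.5) / S
  px <- rep(grid_c, each = S)            # column-major: row index fastest
  py <- rep(rev(grid_c), times = S)      # y up
  s <- params$scale / 0.7
  cx <- 0.46 + params$position[1L]
  cy <- 0.50 + params$position[2L]
  ax <- 0.165 * s * params$body_aspect
  ay <- 0.078 * s
  deg <- pi / 180
  mask <- .in_ellipse(px, py, cx, cy, ax, ay)
  # legs: two pairs of axis-aligned rectangles
  lw <- 0.026 * s
  y_top <- cy
  y_bot <- cy - 0.25 * s
  for (sign_ in c(-1, 1)) {
    base_x <- cx + sign_ * ax * 0.62
    for (off in c(-1, 1) * 0.024 * params$leg_spread) {
      lx <- base_x + off
      mask <- mask | (abs(px - lx) <= lw / 2 & py >= y_bot & py <= y_top)
    }
  }
  # neck: wide strip so the angle reads even at coarse resolution
  na_ <- params$neck_angle * deg
  p0 <- c(cx + ax * 0.72, cy + ay * 0.3)
  dn <- c(cos(na_), sin(na_))
  ln <- 0.16 * s
  p_neck <- p0 + dn * ln
  mask <- mask | .in_quad(px, py, .quad_strip(p0, p_neck, 0.085 * s, 0.055 * s))
  # head: oriented along the neck axis rotated down by head_drop
  ha <- na_ - params$head_drop * deg
  dh <- c(cos(ha), sin(ha))
  hc <- p_neck + dh * 0.045 * s
  mask <- mask | .in_ellipse(px, py, hc[1], hc[2], 0.068 * s, 0.04 * s, ha)
  # tail: strip from the rear, angle above the backward horizontal
  ta <- params$tail_angle * deg
  p1 <- c(cx - ax * 0.9, cy + ay * 0.3)
  dt <- c(-cos(ta), sin(ta))
  p_tail <- p1 + dt * 0.16 * s
  mask <- mask | .in_quad(px, py, .quad_strip(p1, p_tail, 0.045 * s, 0.028 * s))
  matrix(mask, S, S)
}

#' Render a posture silhouette image
#'
#' @param params A [silhouette_params()] object.
#' @param image_size Pixels per side.
#' @param fg,bg Foreground / background intensities.
#' @return Grayscale matrix in \[0, 1\] with attribute `"mask"` (logical
#'   foreground mask).
#' @export
render_silhouette <- function(params, image_size, fg = 0.15, bg = 0.85) {
  mask <- render_silhouette_mask(params, image_size)
  img <- matrix(bg, nrow(mask), ncol(mask))
  img[mask] <- fg
  attr(img, "mask") <- mask
  img
}

# draw jittered params for class `emotion` from `rng`
.draw_params <- function(emotion, rng) {
  silhouette_params(
    emotion,
    jitter = rng_runif(rng, 3, -4, 4),
    body_aspect = 1 + rng_runif(rng, 1, -0.05, 0.05),
    leg_spread = 1 + rng_runif(rng, 1, -0.15, 0.15),
    scale = 0.7 + rng_runif(rng, 1, -0.03, 0.03),
    position = rng_runif(rng, 2, -0.012, 0.012)
  )
}

.finish_image <- function(img, spec, rng) {
  if (spec$blur_prob > 0 && rng_runif(rng, 1) < spec$blur_prob) {
    img <- gaussian_blur(img, 5L, 1)
  }
  if (spec$noise_sd > 0) {
    img <- img + rng_rnorm(rng, length(img), sd = spec$noise_sd)
  }
  matrix(pmin(pmax(img, 0), 1), nrow(img), ncol(img))
}

#' Generate a synthetic posture dataset
#'
#' Produces silhouette images plus a dataset manifest whose `emotion` column
#' carries the latent posture class.  Without a `breed_preset` the dataset is
#' exactly balanced (`n_classes * n_per_class` rows, breeds cycled); with a
#' preset, breeds are assigned in blocks matching the given counts and
#' emotions are cycled within each block.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory; when given, images are written as 8-bit
#'   grayscale PNGs and the manifest as `manifest.csv` with paths relative to
#'   `out_dir`.
#' @param render When `FALSE`, skip rasterisation and return only the
#'   manifest (useful for large bookkeeping checks).
#' @return List with elements `images` (list of matrices, or `NULL` when
#'   `render = FALSE`) and `manifest` (data.frame `path,breed,emotion,split`).
#' @export
generate_posture_dataset <- function(spec, out_dir = NULL, render = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  emos <- emotion_levels()[seq_len(spec$n_classes)]
  if (!is.null(spec$breed_preset)) {
    breeds <- rep(names(spec$breed_preset), times = spec$breed_preset)
    n <- length(breeds)
    emotion <- unlist(lapply(spec$breed_preset, function(k) {
      rep_len(emos, k)
    }), use.names = FALSE)
  } else {
    n <- spec$n_classes * spec$n_per_class
    emotion <- rep(emos, each = spec$n_per_class)
    breeds <- rep_len(names(wild_horse_breed_counts()), max(n, 1L))[seq_len(n)]
  }
  manifest <- data.frame(
    path = if (n > 0) sprintf("img_%05d.png", seq_len(n)) else character(0),
    breed = if (n > 0) breeds else character(0),
    emotion = if (n > 0) emotion else character(0),
    split = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  manifest <- as_dataset_manifest(manifest)
  images <- NULL
  if (render && n > 0) {
    rng <- rng_new(spec$seed)
    images <- vector("list", n)
    for (i in seq_len(n)) {
      p <- .draw_params(manifest$emotion[i], rng)
      img <- render_silhouette(p, spec$image_size)
      attr(img, "mask") <- NULL
      images[[i]] <- .finish_image(img, spec, rng)
    }
    names(images) <- manifest$path
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (render && n > 0) {
      for (i in seq_len(n)) {
        write_image_png(images[[i]], file.path(out_dir, manifest$path[i]))
      }
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(images = images, manifest = manifest, spec = spec)
}

#' Generate a synthetic frame-sequence video
#'
#' Renders `round(n_seconds * fps)` frames, each containing one silhouette of
#' a single latent class drifting slowly across the frame, and records the
#' silhouette's tight bounding box per frame as detector ground truth.
#'
#' @param n_seconds Duration in seconds (> 0).
#' @param fps Frame rate (> 0).
#' @param spec A [fixture_spec()]; `image_size` is the frame side and `seed`
#'   drives all randomness.
#' @param out_dir Optional directory; when given, frames are written as
#'   numbered PNGs plus sidecars `video.json` (`{fps, n_frames}`) and
#'   `boxes.json` (ground-truth boxes, 0-based pixel coordinates).
#' @return List with `frames` (list of matrices), `boxes` (data.frame
#'   `frame,x,y,width,height`), `fps`, `n_frames`.
#' @export
generate_synthetic_video <- function(n_seconds, fps, spec, out_dir = NULL) {
  if (!is.numeric(n_seconds) || n_seconds <= 0) {
    stop("invalid `n_seconds`: must be > 0", call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) {
    stop("invalid `fps`: must be > 0", call. = FALSE)
  }
  stopifnot(inherits(spec, "fixture_spec"))
  n_frames <- round(n_seconds * fps)
  rng <- rng_new(spec$seed)
  emo <- rng_sample(rng, emotion_levels()[seq_len(spec$n_classes)], 1L)
  # linear drift path, kept small so the silhouette stays in frame
  drift <- rng_runif(rng, 2, -0.03, 0.03)
  S <- spec$image_size
  frames <- vector("list", n_frames)
  boxes <- data.frame(frame = integer(0), x = integer(0), y = integer(0),
                      width = integer(0), height = integer(0))
  for (f in seq_len(n_frames)) {
    t_ <- (f - 1) / max(n_frames - 1, 1)
    p <- .draw_params(emo, rng)
    p$position <- pmin(pmax(p$position + drift * (t_ - 0.5), -0.04), 0.04)
    img <- render_silhouette(p, S)
    mask <- attr(img, "mask")
    attr(img, "mask") <- NULL
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    boxes <- rbind(boxes, data.frame(
      frame = f - 1L, x = cols[1] - 1L, y = rows[1] - 1L,
      width = cols[2] - cols[1] + 1L, height = rows[2] - rows[1] + 1L))
    frames[[f]] <- .finish_image(img, spec, rng)
  }
  out <- list(frames = frames, boxes = boxes, fps = fps, n_frames = n_frames)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in seq_len(n_frames)) {
      write_image_png(frames[[f]], file.path(out_dir, sprintf("frame_%05d.png", f - 1L)))
    }
    jsonlite::write_json(list(fps = fps, n_frames = n_frames),
                         file.path(out_dir, "video.json"), auto_unbox = TRUE)
    jsonlite::write_json(boxes, file.path(out_dir, "boxes.json"))
    out$dir <- out_dir
  }
  out
}

#' Certify that a fixture set is learnable
#'
#' Trains a nearest-class-centroid rule in raw pixel space on the first half
#' of each class and reports held-out accuracy on the second half.  Used as a
#' sanity oracle: downstream representation-learning tests only mean something
#' if the fixtures themselves are separable.
#'
#' @param images List of grayscale matrices, aligned with `manifest` rows.
#' @param manifest Dataset manifest carrying the latent class in `emotion`.
#' @return Held-out accuracy as a fraction in \[0, 1\].
#' @export
fixture_separability_check <- function(images, manifest) {
  labs <- manifest$emotion
  classes <- unique(labs)
  if (length(classes) < 2L) {
    stop("need >= 2 classes for a separability check", call. = FALSE)
  }
  counts <- table(labs)
  if (any(counts < 4L)) {
    stop("need >= 4 images per class for a separability check", call. = FALSE)
  }
  X <- vapply(images, as.vector, numeric(length(images[[1L]])))
  train_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(labs == cl)
    idx[seq_len(floor(length(idx) / 2))]
  }))
  test_idx <- setdiff(seq_along(labs), train_idx)
  centroids <- vapply(classes, function(cl) {
    rowMeans(X[, intersect(train_idx, which(labs == cl)), drop = FALSE])
  }, numeric(nrow(X)))
  d2 <- vapply(seq_along(classes), function(k) {
    colSums((X[, test_idx, drop = FALSE] - centroids[, k])^2)
  }, numeric(length(test_idx)))
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred == labs[test_idx])
}
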