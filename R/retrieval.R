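# Video -> crop retrieval: frame downsampling, a pluggable detector
# interface, and the crop quality filters (minimum resolution and a cap on
# the standard deviation of [0,1]-scaled pixel intensities).

#' Plan which frames of a video to process
#'
#' Footage shot at a high frame rate is downsampled to a much lower effective
#' rate (default 0.1 frames per second) before detection, by keeping every
#' `round(source_fps / target_fps)`-th frame starting at frame 0.
#'
#' @param n_frames Total number of frames in the video.
#' @param source_fps Source frame rate (>= `target_fps`).
#' @param target_fps Effective rate after downsampling (> 0).
#' @return A `frame_sample_plan`: list with `source_fps`, `target_fps`,
#'   `stride` and 0-based `selected_indices` (strictly increasing, constant
#'   stride).
#' @export
sample_frames <- function(n_frames, source_fps, target_fps = 0.1) {
  if (!is.numeric(target_fps) || target_fps <= 0) {
    stop("`target_fps` must be > 0", call. = FALSE)
  }
  if (target_fps > source_fps) {
    stop("`target_fps` (", target_fps, ") exceeds `source_fps` (",
         source_fps, ")", call. = FALSE)
  }
  stopifnot(n_frames >= 0)
  stride <- max(1L, as.integer(round(source_fps / target_fps)))
  idx <- if (n_frames > 0) seq.int(0L, n_frames - 1L, by = stride) else integer(0)
  structure(list(source_fps = source_fps, target_fps = target_fps,
                 stride = stride, selected_indices = as.integer(idx)),
            class = "frame_sample_plan")
}

#' Detector interface and bundled implementations
#'
#' A detector is a list with a `detect(frame)` function returning a
#' data.frame of scored boxes (`x,y,width,height,score`; 0-based top-left
#' offsets) and a `name`.  [stub_detector()] is always available: it
#' thresholds the frame (synthetic silhouettes are dark on a light
#' background) and returns one box per connected foreground component, which
#' reproduces the fixture generator's ground-truth boxes.  An adapter for an
#' external object detector can be plugged in with [make_detector()].
#'
#' @param threshold Intensity below which a pixel counts as foreground.
#' @param min_area Minimum component size in pixels (suppresses noise specks).
#' @return A `detector` object.
#' @export
stub_detector <- function(threshold = 0.5, min_area = 9L) {
  detect_fn <- function(frame) {
    fg <- to_grayscale(frame) < threshold
    comps <- .label_components(fg)
    if (comps$n == 0L) return(.empty_boxes())
    out <- do.call(rbind, lapply(seq_len(comps$n), function(id) {
      cells <- which(comps$labels == id, arr.ind = TRUE)
      if (nrow(cells) < min_area) return(NULL)
      data.frame(x = min(cells[, 2]) - 1L, y = min(cells[, 1]) - 1L,
                 width = diff(range(cells[, 2])) + 1L,
                 height = diff(range(cells[, 1])) + 1L,
                 score = 0.99)
    }))
    if (is.null(out)) .empty_boxes() else out
  }
  make_detector(detect_fn, name = "stub")
}

#' @rdname stub_detector
#' @param detect_fn Function `frame -> data.frame(x,y,width,height,score)`.
#' @param name Detector name recorded in run reports.
#' @export
make_detector <- function(detect_fn, name = "external") {
  stopifnot(is.function(detect_fn))
  structure(list(detect = detect_fn, name = name), class = "detector")
}

.empty_boxes <- function() {
  data.frame(x = integer(0), y = integer(0), width = integer(0),
             height = integer(0), score = numeric(0))
}

# 8-connected component labelling by iterative flood fill (diagonal
# adjacency keeps thin rasterised limbs attached); frames are small so a
# stack-based fill in R is fine.
.label_components <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  labels <- matrix(0L, h, w)
  n <- 0L
  todo <- which(fg & labels == 0L)
  while (length(todo) > 0L) {
    seed_ <- todo[1L]
    n <- n + 1L
    stack <- seed_
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (labels[cur] != 0L || !fg[cur]) next
      labels[cur] <- n
      r <- (cur - 1L) %% h + 1L
      cc <- (cur - 1L) %/% h + 1L
      nb <- integer(0)
      for (dc in -1:1) for (dr in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w) {
          nb <- c(nb, (c2 - 1L) * h + r2)
        }
      }
      nb <- nb[fg[nb] & labels[nb] == 0L]
      if (length(nb)) stack <- c(stack, nb)
    }
    todo <- which(fg & labels == 0L)
  }
  list(labels = labels, n = n)
}

#' Run a detector on one frame
#'
#' @param frame Grayscale matrix (or RGB array).
#' @param detector A `detector` object.
#' @return Data.frame of boxes clipped to the frame bounds, sorted by
#'   descending score.
#' @export
detect <- function(frame, detector) {
  if (!inherits(detector, "detector")) {
    stop("no detector registered: pass a `detector` object ",
         "(the stub detector is always available)", call. = FALSE)
  }
  g <- to_grayscale(frame)
  if (length(g) == 0L) stop("empty frame", call. = FALSE)
  boxes <- detector$detect(frame)
  if (nrow(boxes) == 0L) return(.empty_boxes())
  h <- nrow(g); w <- ncol(g)
  # clip to the half-open frame box [0,w) x [0,h)
  x0 <- pmax(boxes$x, 0L); y0 <- pmax(boxes$y, 0L)
  x1 <- pmin(boxes$x + boxes$width, w); y1 <- pmin(boxes$y + boxes$height, h)
  keep <- x1 > x0 & y1 > y0
  boxes <- data.frame(x = x0[keep], y = y0[keep],
                      width = x1[keep] - x0[keep],
                      height = y1[keep] - y0[keep],
                      score = boxes$score[keep])
  boxes[order(boxes$score, decreasing = TRUE), , drop = FALSE]
}

#' Quality-filter a crop
#'
#' A crop passes when both sides are at least `min_side` pixels and the
#' standard deviation of its \[0,1\]-scaled grayscale intensities is below
#' `sigma_threshold` (the printed acceptance inequality sigma_x < 0.4; for
#' intensities bounded in \[0,1\] sigma_x can never exceed 0.5).  The
#' resolution check is applied first.
#'
#' @param crop Grayscale matrix in \[0, 1\].
#' @param min_side Minimum acceptable side length in pixels.
#' @param sigma_threshold Acceptance bound on the intensity standard
#'   deviation.
#' @return A `crop_quality_report`: list with `width`, `height`, `sigma_x`,
#'   `accepted`, `reject_reason` (one of `"none"`, `"resolution"`,
#'   `"intensity_sd"`).
#' @export
filter_crop <- function(crop, min_side = 250L, sigma_threshold = 0.4) {
  g <- to_grayscale(crop)
  if (length(g) == 0L) stop("empty crop", call. = FALSE)
  h <- nrow(g); w <- ncol(g)
  # population standard deviation of the scaled intensities
  sigma_x <- sqrt(mean((g - mean(g))^2))
  if (min(h, w) < min_side) {
    reason <- "resolution"
  } else if (sigma_x >= sigma_threshold) {
    reason <- "intensity_sd"
  } else {
    reason <- "none"
  }
  structure(list(width = w, height = h, sigma_x = sigma_x,
                 accepted = reason == "none", reject_reason = reason),
            class = "crop_quality_report")
}

.read_video_meta <- function(video_dir) {
  meta_path <- file.path(video_dir, "video.json")
  if (!file.exists(meta_path)) {
    stop("unreadable video (missing video.json): ", video_dir, call. = FALSE)
  }
  jsonlite::read_json(meta_path, simplifyVector = TRUE)
}

#' Extract a filtered crop dataset from videos
#'
#' Runs the full retrieval pipeline over frame-directory videos: sample
#' frames at `target_fps`, detect animals, crop each detection, apply the
#' quality filters, and save accepted crops with provenance.  Unreadable
#' videos are recorded as errors and skipped; the run continues.
#'
#' @param video_dirs Character vector of video directories (numbered PNG
#'   frames plus a `video.json` sidecar).
#' @param detector A `detector` object (see [stub_detector()]).
#' @param target_fps Effective sampling rate.
#' @param min_side,sigma_threshold Filter parameters, see [filter_crop()].
#' @param out_dir Optional output directory for crops + manifest +
#'   `report.json`.
#' @param breed Breed recorded in the manifest (one value, or one per video).
#' @return List with `crops` (list of matrices), `manifest`, and `report`
#'   (counts: detected, accepted, rejected by reason, per-video errors).
#' @export
extract_dataset <- function(video_dirs, detector = stub_detector(),
                            target_fps = 0.1, min_side = 250L,
                            sigma_threshold = 0.4, out_dir = NULL,
                            breed = "unknown") {
  if (length(video_dirs) == 0L) {
    stop("no videos supplied", call. = FALSE)
  }
  breed <- rep_len(breed, length(video_dirs))
  crops <- list()
  rows <- list()
  report <- list(detected = 0L, accepted = 0L,
                 rejected_resolution = 0L, rejected_intensity_sd = 0L,
                 errors = character(0))
  for (v in seq_along(video_dirs)) {
    vdir <- video_dirs[v]
    meta <- tryCatch(.read_video_meta(vdir), error = function(e) e)
    if (inherits(meta, "error")) {
      report$errors <- c(report$errors, paste0(vdir, ": ", conditionMessage(meta)))
      next
    }
    plan <- sample_frames(meta$n_frames, meta$fps, target_fps)
    for (fi in plan$selected_indices) {
      fpath <- file.path(vdir, sprintf("frame_%05d.png", fi))
      frame <- tryCatch(read_image_png(fpath), error = function(e) e)
      if (inherits(frame, "error")) {
        report$errors <- c(report$errors, paste0(fpath, ": unreadable frame"))
        next
      }
      boxes <- detect(frame, detector)
      report$detected <- report$detected + nrow(boxes)
      for (b in seq_len(nrow(boxes))) {
        bx <- boxes[b, ]
        crop <- frame[(bx$y + 1):(bx$y + bx$height),
                      (bx$x + 1):(bx$x + bx$width), drop = FALSE]
        rep_ <- filter_crop(crop, min_side, sigma_threshold)
        if (!rep_$accepted) {
          key <- paste0("rejected_", rep_$reject_reason)
          report[[key]] <- report[[key]] + 1L
          next
        }
        report$accepted <- report$accepted + 1L
        crop_name <- sprintf("crop_v%02d_f%05d_b%02d.png", v, fi, b)
        crops[[crop_name]] <- crop
        rows[[length(rows) + 1L]] <- data.frame(
          path = crop_name, breed = breed[v], emotion = NA_character_,
          split = NA_character_, video = basename(vdir), frame = fi,
          box_x = bx$x, box_y = bx$y, box_w = bx$width, box_h = bx$height,
          stringsAsFactors = FALSE)
      }
    }
  }
  prov <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0), breed = character(0),
               emotion = character(0), split = character(0))
  manifest <- as_dataset_manifest(prov[, c("path", "breed", "emotion", "split")])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(crops)) write_image_png(crops[[nm]], file.path(out_dir, nm))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE)
    if (nrow(prov) > 0) {
      utils::write.csv(prov, file.path(out_dir, "provenance.csv"),
                       row.names = FALSE)
    }
  }
  list(crops = crops, manifest = manifest, provenance = prov, report = report)
}
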