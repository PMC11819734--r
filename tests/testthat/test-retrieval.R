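test_that("frame sampling keeps a constant stride anchored at frame 0", {
  p <- sample_frames(300, 30, 0.1)
  expect_identical(p$selected_indices, 0L)
  expect_identical(p$stride, 300L)

  p <- sample_frames(1800, 30, 0.1)
  expect_identical(p$selected_indices, as.integer(seq(0, 1500, by = 300)))
  expect_length(p$selected_indices, 6L)

  p <- sample_frames(25, 30, 30)
  expect_identical(p$selected_indices, 0:24)  # target = source: every frame

  expect_error(sample_frames(100, 30, 31), "exceeds")
  expect_error(sample_frames(100, 30, 0), "target_fps")
})

test_that("frame sampling agrees with a timestamp-walking oracle", {
  # oracle: emit one frame per 1/target_fps seconds starting at t = 0
  oracle <- function(n_frames, source_fps, target_fps) {
    idx <- integer(0)
    t <- 0
    repeat {
      f <- round(t * source_fps)
      if (f >= n_frames) break
      idx <- c(idx, f)
      t <- t + 1 / target_fps
    }
    as.integer(idx)
  }
  grid <- expand.grid(source = c(10, 24, 25, 30, 60),
                      target = c(0.1, 0.5, 1, 2, 5),
                      n = c(57, 300, 1001))
  # the stride contract matches the oracle whenever the rate ratio is integral
  grid <- grid[abs(grid$source / grid$target -
                     round(grid$source / grid$target)) < 1e-9, ]
  for (g in seq_len(nrow(grid))) {
    p <- sample_frames(grid$n[g], grid$source[g], grid$target[g])
    expect_identical(p$selected_indices,
                     oracle(grid$n[g], grid$source[g], grid$target[g]),
                     label = paste("grid row", g))
  }
})

test_that("the stub detector echoes the generator's ground-truth boxes", {
  spec <- fixture_spec(seed = 12L, noise_sd = 0)
  v <- generate_synthetic_video(0.5, 4, spec)  # 2 frames
  for (f in seq_along(v$frames)) {
    det <- detect(v$frames[[f]], stub_detector())
    expect_identical(nrow(det), 1L)
    truth <- v$boxes[v$boxes$frame == f - 1L, ]
    expect_identical(as.integer(det$x), truth$x)
    expect_identical(as.integer(det$y), truth$y)
    expect_identical(as.integer(det$width), truth$width)
    expect_identical(as.integer(det$height), truth$height)
  }
})

test_that("detection contract: empty frames, score ordering, clipping", {
  blank <- matrix(0.85, 40, 40)
  expect_identical(nrow(detect(blank, stub_detector())), 0L)

  two_boxes <- make_detector(function(frame) {
    data.frame(x = c(1L, 10L), y = c(1L, 10L), width = c(5L, 5L),
               height = c(5L, 5L), score = c(0.7, 0.9))
  })
  det <- detect(blank, two_boxes)
  expect_identical(det$score, c(0.9, 0.7))

  overflow <- make_detector(function(frame) {
    data.frame(x = 35L, y = -2L, width = 10L, height = 10L, score = 0.5)
  })
  det <- detect(blank, overflow)
  expect_identical(det$x + det$width, 40L)   # clipped to frame
  expect_identical(det$y, 0L)
  expect_error(detect(blank, "not a detector"), "detector")
})

test_that("crop filtering applies resolution then intensity-sd rules", {
  r <- filter_crop(matrix(0.5, 300, 240))
  expect_false(r$accepted)
  expect_identical(r$reject_reason, "resolution")

  r <- filter_crop(matrix(0.37, 250, 250))
  expect_identical(r$sigma_x, 0)
  expect_true(r$accepted)

  half <- cbind(matrix(0, 256, 128), matrix(1, 256, 128))
  r <- filter_crop(half)
  # balanced two-point distribution: sigma is exactly 0.5
  expect_equal(r$sigma_x, 0.5, tolerance = 1e-12)
  expect_false(r$accepted)
  expect_identical(r$reject_reason, "intensity_sd")

  # the filter is a pure function of the pixels
  expect_identical(filter_crop(half), filter_crop(half))
})

test_that("sigma_x stays within its theoretical range on random crops", {
  rng <- rng_new(8L)
  for (i in 1:20) {
    img <- matrix(rng_runif(rng, 900), 30, 30)
    r <- filter_crop(img, min_side = 10)
    expect_gte(r$sigma_x, 0)
    expect_lte(r$sigma_x, 0.5)
    expect_identical(r$accepted, r$reject_reason == "none")
  }
})

test_that("extraction pipeline yields one crop per sampled frame and logs rejects", {
  spec <- fixture_spec(image_size = 64L, seed = 3L)
  vdir <- file.path(withr::local_tempdir(), "vid1")
  generate_synthetic_video(60, 1, spec, out_dir = vdir)  # 60 frames at 1 fps

  out <- extract_dataset(vdir, stub_detector(), target_fps = 0.1,
                         min_side = 10L, sigma_threshold = 0.4)
  # 60 frames at 1 fps sampled to 0.1 fps -> 6 frames, one silhouette each
  expect_length(out$crops, 6L)
  expect_identical(out$report$accepted, 6L)
  expect_identical(nrow(out$manifest), 6L)

  # same footage under the full-resolution requirement: everything rejected
  out2 <- extract_dataset(vdir, stub_detector(), target_fps = 0.1,
                          min_side = 250L)
  expect_length(out2$crops, 0L)
  expect_identical(out2$report$rejected_resolution, 6L)

  # conservation: every detection is accepted or rejected for one reason
  for (o in list(out, out2)) {
    expect_identical(o$report$detected,
                     o$report$accepted + o$report$rejected_resolution +
                       o$report$rejected_intensity_sd)
  }
})

test_that("unreadable videos are recorded and the run continues", {
  spec <- fixture_spec(image_size = 64L, seed = 4L)
  base <- withr::local_tempdir()
  vdir <- file.path(base, "ok")
  generate_synthetic_video(10, 1, spec, out_dir = vdir)
  bad <- file.path(base, "broken")
  dir.create(bad)
  out <- extract_dataset(c(bad, vdir), stub_detector(), target_fps = 1,
                         min_side = 10L)
  expect_length(out$report$errors, 1L)
  expect_match(out$report$errors, "broken")
  expect_gt(out$report$accepted, 0L)
  expect_error(extract_dataset(character(0)), "no videos")
})
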