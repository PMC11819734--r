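test_that("dataset size and balance follow the spec of the generator", {
  empty <- generate_posture_dataset(fixture_spec(n_per_class = 0L, seed = 1L))
  expect_null(empty$images)
  expect_identical(nrow(empty$manifest), 0L)

  ds <- small_fixture_set()  # 8 classes x 8 images
  expect_length(ds$images, 64L)
  counts <- table(ds$manifest$emotion)
  expect_setequal(names(counts), emotion_levels())
  # balance: every label equally represented
  expect_true(all(counts == 8L))
})

test_that("the breed preset reproduces the reference 3,929-image bookkeeping", {
  spec <- fixture_spec(breed_preset = wild_horse_breed_counts(), seed = 1L)
  ds <- generate_posture_dataset(spec, render = FALSE)
  expect_identical(nrow(ds$manifest), 3929L)
  expect_identical(
    as.integer(table(ds$manifest$breed)[names(wild_horse_breed_counts())]),
    unname(wild_horse_breed_counts()))
})

test_that("invalid fixture specs are rejected with the offending field named", {
  expect_error(fixture_spec(n_classes = 0), "n_classes")
  expect_error(fixture_spec(n_classes = 9), "n_classes")
  expect_error(fixture_spec(n_per_class = -1), "n_per_class")
  expect_error(fixture_spec(image_size = 16), "image_size")
  expect_error(fixture_spec(noise_sd = -0.1), "noise_sd")
  expect_error(fixture_spec(blur_prob = 2), "blur_prob")
  expect_error(fixture_spec(breed_preset = c(3, 4)), "breed_preset")
})

test_that("identical specs regenerate byte-identical images and files", {
  spec <- fixture_spec(n_per_class = 2L, image_size = 32L, noise_sd = 0.03,
                       blur_prob = 0.3, seed = 77L)
  a <- generate_posture_dataset(spec)
  b <- generate_posture_dataset(spec)
  expect_identical(a$images, b$images)
  expect_identical(a$manifest, b$manifest)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_posture_dataset(spec, out_dir = d1)
  generate_posture_dataset(spec, out_dir = d2)
  for (f in list.files(d1)) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
})

test_that("silhouettes stay inside the frame at scale <= 0.8", {
  for (emo in emotion_levels()) {
    p <- silhouette_params(emo, scale = 0.8)
    m <- attr(render_silhouette(p, 64L), "mask")
    expect_false(any(m[1, ]) || any(m[64, ]) || any(m[, 1]) || any(m[, 64]),
                 label = paste("class", emo, "inside frame"))
  }
})

test_that("latent classes occupy distinct posture-angle regions", {
  tab <- posture_class_table <- equimoco:::posture_class_table()
  # pairwise Chebyshev distance in (neck, head, tail) must exceed the 8-degree
  # jitter box so jittered classes can never overlap
  ang <- as.matrix(tab[, c("neck_angle", "head_drop", "tail_angle")])
  for (i in 1:(nrow(ang) - 1)) for (j in (i + 1):nrow(ang)) {
    expect_gt(max(abs(ang[i, ] - ang[j, ])), 8)
  }
})

test_that("synthetic videos have the contracted frame and box counts", {
  spec <- fixture_spec(seed = 5L)
  v <- generate_synthetic_video(10, 30, spec)
  expect_length(v$frames, 300L)
  v2 <- generate_synthetic_video(6, 10, spec)
  expect_length(v2$frames, 60L)
  expect_identical(nrow(v2$boxes), 60L)  # one silhouette per frame
  # ground-truth boxes are tight: positive sizes inside the frame
  expect_true(all(v2$boxes$width > 0 & v2$boxes$height > 0))
  expect_true(all(v2$boxes$x >= 0 & v2$boxes$x + v2$boxes$width <= 32))
  expect_error(generate_synthetic_video(0, 30, spec), "n_seconds")
  expect_error(generate_synthetic_video(10, -1, spec), "fps")
})

test_that("regenerating a video with the same spec is byte-identical", {
  spec <- fixture_spec(seed = 9L)
  v1 <- generate_synthetic_video(1, 5, spec)
  v2 <- generate_synthetic_video(1, 5, spec)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$boxes, v2$boxes)
})

test_that("separability oracle scores disjoint noiseless classes perfectly", {
  spec <- fixture_spec(n_classes = 2L, n_per_class = 8L, noise_sd = 0,
                       seed = 21L)
  ds <- generate_posture_dataset(spec)
  expect_identical(fixture_separability_check(ds$images, ds$manifest), 1)
})

test_that("separability collapses to the permutation null on shuffled labels", {
  ds <- small_fixture_set()
  rng <- rng_new(404L)
  accs <- replicate(20, {
    man <- ds$manifest
    man$emotion <- rng_sample(rng, man$emotion)
    fixture_separability_check(ds$images, man)
  })
  # Monte-Carlo check of the 1/8 chance level
  expect_lt(abs(mean(accs) - 1 / 8), 0.07)
})

test_that("the learnability gate holds for the default fixture set", {
  ds <- cached("default_fixture", {
    generate_posture_dataset(fixture_spec(noise_sd = 0.05, seed = 31L))
  })
  expect_gte(fixture_separability_check(ds$images, ds$manifest), 0.9)
})

test_that("degenerate separability inputs are refused", {
  ds <- small_fixture_set()
  one_class <- ds$manifest$emotion == "Care"
  expect_error(
    fixture_separability_check(ds$images[one_class],
                               ds$manifest[one_class, ]),
    ">= 2 classes")
  few <- c(which(ds$manifest$emotion == "Care")[1:2],
           which(ds$manifest$emotion == "Fear")[1:2])
  expect_error(
    fixture_separability_check(ds$images[few], ds$manifest[few, ]),
    ">= 4 images")
})
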