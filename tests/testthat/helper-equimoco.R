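# Shared fixtures, generated once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# the default 8-class fixture set at unit-test size
small_fixture_set <- function() {
  cached("small_fixture", {
    generate_posture_dataset(fixture_spec(n_per_class = 8L, image_size = 32L,
                                          noise_sd = 0.02, seed = 101L))
  })
}

# a tiny encoder configuration cheap enough to build repeatedly
tiny_encoder_config <- function(seed = 1L, d = 16L) {
  encoder_config(input_size = 32L, representation_dim = d,
                 conv_channels = c(4L, 4L, 8L, 8L), fc_hidden = 32L,
                 dropout_p = 0.2, seed = seed)
}

random_unit <- function(d, rng) {
  v <- rng_rnorm(rng, d)
  v / sqrt(sum(v^2))
}

# n random unit vectors as columns
random_unit_cols <- function(d, n, rng) {
  m <- matrix(rng_rnorm(rng, d * n), d, n)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}
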