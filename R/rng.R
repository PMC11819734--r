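#' Named random-number generator streams
#'
#' Every stochastic operation in the package draws from an explicit generator
#' object rather than the session's global random state.  A generator is an
#' isolated Mersenne-Twister stream seeded once; drawing from it never touches
#' (and is never affected by) `.Random.seed` in the caller's session.
#'
#' @param seed Integer seed.
#' @return An object of class `equimoco_rng`.
#' @examples
#' r <- rng_new(1)
#' rng_runif(r, 3)
#' @export
rng_new <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  old <- .peek_seed()
  set.seed(as.integer(seed %% .Machine$integer.max))
  e$state <- get(".Random.seed", envir = globalenv())
  .poke_seed(old)
  class(e) <- "equimoco_rng"
  e
}

.peek_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.poke_seed <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Evaluate an expression under a generator's stream
#'
#' Swaps the generator state in, evaluates, and swaps the previous global
#' state back, advancing the generator.
#'
#' @param rng An `equimoco_rng` object.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
rng_eval <- function(rng, expr) {
  stopifnot(inherits(rng, "equimoco_rng"))
  old <- .peek_seed()
  .poke_seed(rng$state)
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    .poke_seed(old)
  }, add = TRUE)
  expr
}

#' @rdname rng_new
#' @param n Number of draws.
#' @param min,max Uniform bounds.
#' @export
rng_runif <- function(rng, n, min = 0, max = 1) {
  rng_eval(rng, stats::runif(n, min, max))
}

#' @rdname rng_new
#' @param mean,sd Normal parameters.
#' @export
rng_rnorm <- function(rng, n, mean = 0, sd = 1) {
  rng_eval(rng, stats::rnorm(n, mean, sd))
}

#' @rdname rng_new
#' @param x,size,replace As in [sample()] (including the scalar-`x`
#'   permutation convention).
#' @export
rng_sample <- function(rng, x, size = NULL, replace = FALSE) {
  if (is.null(size)) {
    rng_eval(rng, sample(x, replace = replace))
  } else {
    rng_eval(rng, sample(x, size, replace))
  }
}

#' Derive a child seed from a generator
#'
#' Used to give sub-operations their own independent streams while keeping
#' everything a pure function of the top-level seed.
#'
#' @param rng An `equimoco_rng` object.
#' @return A single integer below 2^31.
#' @export
rng_child_seed <- function(rng) {
  as.integer(floor(rng_runif(rng, 1) * 2147483646)) + 1L
}
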