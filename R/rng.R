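#' Seeded random source with forkable sub-streams
#'
#' A `rand_source` wraps an independent Mersenne-Twister state so that every
#' stochastic operation in the package draws from an explicit, reproducible
#' stream instead of the global R generator. Identical seed plus identical
#' call sequence gives bit-identical augmentation output, and per-image
#' sub-streams can be forked so that processing order (or parallelism) cannot
#' change results.
#'
#' @param seed Integer seed.
#' @return A `rand_source` object.
#' @examples
#' r <- rand_source(42)
#' rng_runif(r, 3)
#' @export
rand_source <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  e$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  e$seed <- as.integer(seed)
  class(e) <- "rand_source"
  e
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with the stream's state installed; capture the advanced state.
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "rand_source"))
  old <- .save_global_seed()
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    .restore_global_seed(old)
  })
  expr
}

#' Draw uniform variates from a random source
#'
#' @param rng A [rand_source()].
#' @param n Number of draws.
#' @param min,max Interval bounds.
#' @return Numeric vector of length `n`.
#' @export
rng_runif <- function(rng, n, min = 0, max = 1) {
  with_rng(rng, stats::runif(n, min, max))
}

#' Draw uniform integers in `1..k` from a random source
#'
#' @param rng A [rand_source()].
#' @param n Number of draws.
#' @param k Upper bound (inclusive).
#' @return Integer vector of length `n`.
#' @export
rng_rint <- function(rng, n, k) {
  with_rng(rng, sample.int(k, n, replace = TRUE))
}

#' Sample indices without replacement from a random source
#'
#' @param rng A [rand_source()].
#' @param x Vector to sample from.
#' @param size Number of elements.
#' @param replace Sample with replacement?
#' @return Sampled elements.
#' @export
rng_sample <- function(rng, x, size, replace = FALSE) {
  with_rng(rng, {
    if (length(x) == 1 && is.numeric(x)) x <- seq_len(x)
    x[sample.int(length(x), size, replace = replace)]
  })
}

#' Fork an independent sub-stream
#'
#' The child stream's seed is drawn from the parent, so forking advances the
#' parent deterministically and children are mutually independent.
#'
#' @param rng A [rand_source()].
#' @return A new `rand_source`.
#' @export
rng_fork <- function(rng) {
  rand_source(rng_rint(rng, 1, .Machine$integer.max - 1L))
}

#' @export
print.rand_source <- function(x, ...) {
  cat("<rand_source seed=", x$seed, ">\n", sep = "")
  invisible(x)
}
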