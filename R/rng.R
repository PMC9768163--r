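# Named RNG substreams.
#
# A run consumes randomness for four logically independent purposes: network
# construction, population initialization, per-timestep amplification draws,
# and interventions (dissemination messages, replacement redraws). Each gets
# its own stream seeded from the master seed, so e.g. enabling an intervention
# never perturbs the draws of the base dynamics.

# Deterministic 32-bit mix of master seed and stream index; result in
# [1, 2^31 - 2] so it is always a valid set.seed() argument.
derive_seed <- function(seed, stream) {
  offsets <- c(network = 1L, init = 2L, dynamics = 3L, interventions = 4L)
  if (is.character(stream)) {
    stopifnot(stream %in% names(offsets))
    stream <- offsets[[stream]]
  }
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(seed) %% m + 1) * 48271 + as.double(stream) * 1000003
  as.integer(x %% (m - 1)) + 1L
}

#' Create a reproducible random-number stream
#'
#' A stream is an independent source of randomness holding its own RNG state.
#' Drawing from one stream never advances another, and never touches the
#' global RNG state outside of the draw itself.
#'
#' @param seed Integer seed initializing the stream.
#' @return An object of class `soam_rng` from which [stream_runif()] and
#'   [stream_sample()] draw.
#' @examples
#' r <- rng_stream(42)
#' stream_runif(r, 3)
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- NULL
  e$seed <- as.integer(seed)
  class(e) <- "soam_rng"
  e
}

# Swap the stream's state into .Random.seed, evaluate, swap back out.
with_stream <- function(stream, expr) {
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  if (is.null(stream$state)) set.seed(stream$seed) else {
    assign(".Random.seed", stream$state, envir = genv)
  }
  res <- force(expr)
  stream$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  res
}

#' @rdname rng_stream
#' @param stream A `soam_rng` stream.
#' @param n,min,max As in [stats::runif()].
#' @export
stream_runif <- function(stream, n, min = 0, max = 1) {
  with_stream(stream, stats::runif(n, min, max))
}

#' @rdname rng_stream
#' @param x,size As in [sample()] (`x` a vector to sample from).
#' @export
stream_sample <- function(stream, x, size) {
  with_stream(stream, sample(x, size))
}
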