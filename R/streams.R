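# Buffered, keyed RNG streams.
#
# Every stochastic channel of a simulated session (reward rolls, CS rolls,
# shield availability, agent policy draws, self-report noise) draws from its
# own stream, keyed by (master seed, participant, block, channel).  Streams
# are independent of the order in which other channels consume draws, so an
# event log is reproducible even if unrelated parts of the engine are
# refactored.  Draws are buffered in chunks to amortise the cost of
# swapping .Random.seed.

.STREAM_BUFFER <- 512L

#' Derive a 31-bit stream seed from a master seed and a key
#'
#' Deterministic integer hash used to key independent RNG substreams.
#' Kept strictly below 2^31 so the result is a valid R integer seed.
#'
#' @param master_seed integer master seed.
#' @param ... integer key components (participant index, block, channel id).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(master_seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master_seed) %% m
  for (k in as.numeric(c(...))) {
    h <- (h * 48271 + k + 1) %% m
  }
  # one extra mixing round so consecutive keys do not give consecutive seeds
  h <- (h * 69621) %% m
  as.integer(h)
}

#' Create a buffered uniform RNG stream
#'
#' @param seed integer seed for this stream (see [stream_seed()]).
#' @return an environment with buffered draw state.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$state <- NULL   # .Random.seed snapshot, filled lazily
  e$buf <- numeric(0)
  e$pos <- 0L
  e
}

.stream_refill <- function(stream) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  stream$buf <- stats::runif(.STREAM_BUFFER)
  stream$state <- get(".Random.seed", globalenv(), inherits = FALSE)
  stream$pos <- 0L
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  }
  invisible(stream)
}

#' Draw uniforms from a stream
#' @param stream a stream from [rng_stream()].
#' @param n number of draws.
#' @return numeric vector of `n` U(0,1) draws.
#' @export
stream_unif <- function(stream, n = 1L) {
  if (n == 1L) { # fast path used by the event loop
    if (stream$pos >= length(stream$buf)) .stream_refill(stream)
    stream$pos <- stream$pos + 1L
    return(stream$buf[stream$pos])
  }
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    if (stream$pos >= length(stream$buf)) .stream_refill(stream)
    take <- min(n - got, length(stream$buf) - stream$pos)
    out[(got + 1L):(got + take)] <- stream$buf[(stream$pos + 1L):(stream$pos + take)]
    stream$pos <- stream$pos + take
    got <- got + take
  }
  out
}

#' Draw standard normals from a stream (Box-Muller)
#' @inheritParams stream_unif
#' @export
stream_norm <- function(stream, n = 1L) {
  u1 <- stream_unif(stream, n)
  u2 <- stream_unif(stream, n)
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}

#' Draw an exponential variate with given rate
#' @param stream a stream.
#' @param rate exponential rate (> 0); `rate = 0` returns `Inf`.
#' @export
stream_exp <- function(stream, rate) {
  if (rate <= 0) return(Inf)
  -log(stream_unif(stream)) / rate
}

#' Truncated-normal draws via inverse-CDF
#'
#' Exact draws from Normal(mean, sd) conditioned on `[lower, upper]`.
#'
#' @param stream a stream.
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds.
#' @export
stream_truncnorm <- function(stream, n, mean = 0, sd = 1,
                             lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(upper, pmax(lower, mean)), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stream_unif(stream, n)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}
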