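# Named reproducible random substreams. One annealing run owns a family
# of streams (position, operator, payload, Metropolis, reversible) derived
# from a single seed, so ablation modes are variance-paired: disabling a
# component never shifts the draws of the others.

# 32-bit FNV-1a over a character string; exact in doubles (< 2^53)
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    # h * 16777619 mod 2^32, split into 16-bit halves to stay exact
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

#' Deterministic content hash
#'
#' 32-bit FNV-1a style hash of a string, returned as 8 hex digits. Used
#' to fingerprint trajectory logs and configurations.
#'
#' @param x a character scalar (longer vectors are collapsed).
#' @return 8-character hex string.
#' @export
content_hash <- function(x) {
  h <- fnv1a(paste(x, collapse = "\n"))
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# derive a substream seed (< 2^31) from a base seed and a name
sub_seed <- function(seed, name) {
  as.integer(fnv1a(paste0(seed, ":", name)) %% 2147483646) + 1L
}

#' Create a named random substream
#'
#' Streams encapsulate their own `.Random.seed` state; drawing from one
#' never perturbs the global RNG or any other stream.
#'
#' @param seed integer seed.
#' @param name optional stream name mixed into the seed derivation.
#' @return an environment of class `rng_stream`.
#' @export
rng_stream <- function(seed, name = "") {
  s <- if (nzchar(name)) sub_seed(seed, name) else as.integer(seed)
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(s)
  e$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  class(e) <- "rng_stream"
  e
}

# evaluate expr under the stream's RNG state, capturing the advanced state
stream_eval <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Uniform draws from a stream
#' @param stream an `rng_stream`.
#' @param n number of draws.
#' @return numeric vector.
#' @export
stream_runif <- function(stream, n = 1L) stream_eval(stream, stats::runif(n))

#' Sample one index from 1..k uniformly
#' @param stream an `rng_stream`.
#' @param k upper bound (>= 1).
#' @return integer in 1..k.
#' @export
stream_index <- function(stream, k) {
  stopifnot(k >= 1L)
  if (k == 1L) return(1L)
  stream_eval(stream, sample.int(k, 1L))
}

#' Sample one index from a categorical distribution
#' @param stream an `rng_stream`.
#' @param prob non-negative weights (normalized internally).
#' @return integer index.
#' @export
stream_categorical <- function(stream, prob) {
  stopifnot(length(prob) >= 1L, all(prob >= 0), sum(prob) > 0)
  p <- prob / sum(prob)
  u <- stream_runif(stream)
  as.integer(findInterval(u, cumsum(p)) + 1L)
}
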