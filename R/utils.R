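#' @useDynLib chaosesn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package functions never disturb the user's
# random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream seed from a base seed and counters
#'
#' Counter-based seed derivation for replicate sweeps: each (grid point,
#' replicate, stream) combination gets its own reproducible seed without any
#' coordination between runs. Uses a Lehmer-style multiplicative congruential
#' mix modulo the Mersenne prime 2^31 - 1, so results always fit a 32-bit
#' integer and are never 0.
#'
#' @param base_seed Integer base seed.
#' @param ... Additional non-negative integer counters (e.g. grid point
#'   index, replicate index, stream label index), mixed in order.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, ...) {
  m <- 2147483647  # 2^31 - 1
  s <- (abs(as.numeric(base_seed)) %% m)
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(if (s == 0) 1 else s)
}
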