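#' Derive a named random stream seed from a root seed
#'
#' Every generator in the package draws from its own named stream derived from
#' a single root seed, so that adding or reordering generators never perturbs
#' the output of the others. The derivation is a fixed polynomial hash of the
#' stream name folded into the root seed, reduced modulo a prime below 2^31.
#'
#' @param seed Non-negative integer root seed.
#' @param stream Character scalar naming the stream (e.g. `"panel"`).
#' @return An integer seed suitable for [set.seed()].
#' @keywords internal
derive_stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, is.character(stream))
  m <- 2147483629  # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer((seed %% m * 48271 + h) %% m)
}

#' Evaluate code under a derived stream seed, restoring RNG state afterwards
#' @keywords internal
#' @noRd
with_stream_seed <- function(seed, stream, code) {
  withr::with_seed(derive_stream_seed(seed, stream), code)
}
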