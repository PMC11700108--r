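#' Derive a reproducible sub-seed from a root seed and a stage label
#'
#' All randomness in the pipeline flows from one root seed; each stage draws
#' from its own named substream so that adding a stage never perturbs the
#' others. The derivation is a polynomial rolling hash of
#' `"<seed>/<label>"` modulo the Mersenne prime 2^31 - 1, folded into the
#' positive signed-integer range (R seeds are 32-bit).
#'
#' @param seed integer root seed.
#' @param label character scalar naming the substream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate") != derive_seed(1, "split")
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  bytes <- utf8ToInt(paste0(format(as.integer(seed)), "/", label))
  p <- 2147483647          # 2^31 - 1; 65599 * p fits a double exactly
  h <- 17
  for (b in bytes) h <- (h * 65599 + b) %% p
  as.integer(h %% (p - 1)) + 1L
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
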