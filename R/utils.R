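# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a label
#'
#' Every source of randomness in the package flows from one master seed; stages
#' that need independent streams derive a child seed from the master seed plus a
#' stage label, so any stage can be rerun in isolation with the same stream.
#'
#' @param seed master seed (single number).
#' @param label character label naming the consumer (e.g. `"fold2"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(abs(seed) %% 2147483647)
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(max(1, h))
}

# Run expr with a locally-set RNG state; never leaks global state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Tolerant float comparison used for grid/index arithmetic.
.eps <- 1e-9
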