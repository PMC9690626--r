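# internal helpers

#' @importFrom withr with_seed
NULL

# round half away from zero at `digits` decimals (presentation rounding;
# base round() is banker's rounding and disagrees on exact halves)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run `expr` under a fixed RNG seed without disturbing the caller's stream
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
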