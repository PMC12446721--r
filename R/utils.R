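# Internal helpers shared across modules.

# Round half away from zero (documented rounding rule for prorated scores
# and control-pool sizes; base round() rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Seed-splitting scheme: every sub-draw of a larger procedure uses
# stage_seed(seed, k) for a documented stage index k, so any stage can be
# reproduced in isolation. Kept strictly below 2^31 - 1.
stage_seed <- function(seed, stage) {
  (as.double(seed) %% 100000L) * 10007 + stage
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_scaleval <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop_scaleval(name, " must be a single number ",
                  if (open) "strictly inside (0, 1)" else "in [0, 1]",
                  ", got ", deparse(substitute(x)))
  }
  invisible(x)
}
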