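# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even, which does
# not reproduce printed summary percentages).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate expr with a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with the call suppressed; all user-facing errors go through this.
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sense-strand complement for single reference-forward bases.
complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}
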