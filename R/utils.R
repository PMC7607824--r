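# Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state without touching the caller's
# stream.  All stochastic entry points funnel through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  withr::with_seed(as.integer(seed), expr)
}

# Draw n reproducible sub-seeds from a parent seed (kept below 2^31).
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Modal label of a character vector with tie-breaking by the order of
# `levels` (vocabulary order).  Returns list(label, count, tie).
modalLabel <- function(x, levels = NULL) {
  if (length(x) == 0L) stop("cannot take the mode of an empty vector", call. = FALSE)
  if (is.null(levels)) levels <- unique(x)
  tab <- table(factor(x, levels = levels))
  top <- max(tab)
  winners <- names(tab)[tab == top]
  list(label = winners[1L], count = as.integer(top), tie = length(winners) > 1L)
}

stopIfNot <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}
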