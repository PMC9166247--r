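# internal helpers shared across modules

# Run `expr` under a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards so generators never leak global RNG state.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

assertFraction <- function(x, name, lo = 0, hi = 1,
                           openLo = TRUE, openHi = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (openLo) x > lo else x >= lo) && (if (openHi) x < hi else x <= hi)
  if (!ok)
    stop(sprintf("'%s' must be in %s%g, %g%s", name,
                 if (openLo) "(" else "[", lo, hi,
                 if (openHi) ")" else "]"), call. = FALSE)
  as.numeric(x)
}
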