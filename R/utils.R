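# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards. Keeps package randomness out of the user's stream and
# lets the synthetic generator draw each component from its own sub-stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sub-stream seed for a named component of a master seed; stays below 2^31.
substream_seed <- function(seed, component) {
  offsets <- c(outcomes = 11L, covariates = 23L, popq = 37L, mc = 53L)
  (as.integer(seed) * 101L + offsets[[component]]) %% .Machine$integer.max
}

fmt_pct <- function(x, digits = 1) round(100 * x, digits)
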