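# internal helpers shared across modules

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopDegenerate <- function(msg) {
  stop(errorCondition(msg,
                      class = c("tasselcount_degenerate", "error",
                                "condition")))
}

clamp255 <- function(x) pmin(255L, pmax(0L, as.integer(round(x))))
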