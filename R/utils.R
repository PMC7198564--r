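## Internal helpers: seeded evaluation and seed-stream derivation.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All randomness in the package flows through this helper.
withSeed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is required for reproducibility", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a substream seed from a top-level seed, so that stage k of a
## pipeline draws from an independent, reproducible stream. Kept below
## 2^31 - 1 (R integers are 32-bit). Lehmer-style multiplicative step.
deriveSeed <- function(seed, stream) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(stream)) s <- (s * 48271) %% m
  as.integer(s)
}

## Tolerant "x is an integer multiple of y" for times on a grid.
isMultiple <- function(x, y, tol = 1e-8) {
  r <- x / y
  abs(r - round(r)) < tol
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
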