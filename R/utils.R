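#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats runif rnorm predict
#' @importFrom utils head write.csv read.csv
NULL

# Run `expr` under a local RNG stream seeded with `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb user-level randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic half-up rounding (R's round() is round-half-even).
roundHalfUp <- function(x) floor(x + 0.5)

# Derive a per-stage child seed from a root seed; keeps results < 2^31.
deriveSeed <- function(seed, stage, index = 0L) {
  (as.double(seed) * 48271 + match(stage, c(
    "generate", "split", "preprocess", "segment", "network", "features",
    "train", "tune", "evaluate", "bench"
  ), nomatch = 11L) * 7919 + as.double(index) * 104729) %% 2147483647
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
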