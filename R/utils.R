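# Internal helpers shared across modules.

#' @importFrom stats runif setNames
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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

# Deterministic sub-seed derivation; keeps results < 2^31.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647L)
}

# Polynomial rolling hash over a non-negative integer vector, mod 2^31 - 1.
hashTokens <- function(tokens) {
  h <- 17
  for (t in tokens) h <- (h * 131 + t) %% 2147483647
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopUsage <- function(msg) {
  cond <- structure(class = c("ecbsUsageError", "error", "condition"),
                    list(message = msg, call = NULL))
  stop(cond)
}

assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
}
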