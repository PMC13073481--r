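# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
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

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000 + stream) %% .Machine$integer.max)
}

stopIfNot01 <- function(p, what = "p-values") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(what, " must lie in [0, 1]")
  invisible(p)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Branchless ELU family: exp(pmin(a, 0)) equals 1 wherever a > 0, which
# makes the first derivative free of conditionals.
elu  <- function(a) pmax(a, 0) + exp(pmin(a, 0)) - 1
eluD <- function(a) exp(pmin(a, 0))                     # first derivative
eluD2 <- function(a) (a <= 0) * exp(pmin(a, 0))         # second derivative
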