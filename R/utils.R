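#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min &&
    x == trunc(x)
}

is_scalar_num <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

# z-score a vector with sd denominator n-1; errors on constant input
zscore <- function(x, label = "vector") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("cannot z-score constant %s", label)
  (x - mean(x)) / s
}
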