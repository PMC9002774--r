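#' @keywords internal
"_PACKAGE"

#' @importFrom stats var sd cor pt fft mvfft qpois rnorm runif rpois rlnorm
#'   coef lm approx median quantile mad predict
#' @importFrom utils write.csv read.csv head tail combn
NULL

# Run an expression with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, kept within 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629)
}

stopifnot_finite <- function(x, what = "signal") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
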