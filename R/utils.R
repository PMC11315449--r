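#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov lm.fit prcomp rnorm runif sd var predict quantile
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a child seed from a parent seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

as_matrix2 <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid(what, " must be a numeric matrix")
  }
  storage.mode(x) <- "double"
  x
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
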