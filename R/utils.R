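#' Logistic sigmoid and its derivative
#'
#' `sigmoid()` maps pre-activations to rates in (0, 1); `dsigmoid_u()` is the
#' derivative expressed in terms of the pre-activation u, and `dsigmoid_z()`
#' the same derivative expressed in terms of the rate z = sigmoid(u),
#' i.e. z * (1 - z).
#'
#' @param u numeric vector or matrix of pre-activations.
#' @param z numeric vector or matrix of rates in (0, 1).
#' @return Numeric object of the same shape as the input.
#' @export
sigmoid <- function(u) 1 / (1 + exp(-u))

#' @rdname sigmoid
#' @export
dsigmoid_u <- function(u) {
  z <- sigmoid(u)
  z * (1 - z)
}

#' @rdname sigmoid
#' @export
dsigmoid_z <- function(z) z * (1 - z)

## run code under a local RNG state, leaving the caller's stream untouched
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

## dimension check that names the offending matrix in its error message
check_dims <- function(W, n_row, n_col, name) {
  if (!is.matrix(W) || nrow(W) != n_row || ncol(W) != n_col) {
    stop(sprintf("matrix '%s' must be %d x %d (got %s)", name, n_row, n_col,
                 if (is.matrix(W)) paste(dim(W), collapse = " x ") else "non-matrix"),
         call. = FALSE)
  }
  invisible(W)
}

check_len <- function(x, n, name) {
  if (length(x) != n) {
    stop(sprintf("vector '%s' must have length %d (got %d)", name, n, length(x)),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("vector '%s' contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

## one-hot encoding of integer labels 1..k
one_hot <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}
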