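#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic step in the package draws its own seed from the master
#' seed plus a path of string/integer keys, so that a single `masterSeed`
#' pins down all 41 x 25 x 2 modularity runs, the null realizations, and
#' the synthetic generators. The derivation is a multiplicative
#' linear-congruential mix modulo the Mersenne prime 2^31 - 1, keeping all
#' intermediates exactly representable in doubles.
#'
#' @param seed Integer master seed.
#' @param ... Character or integer keys identifying the consumer
#'   (e.g. `"net"`, gamma index, run index).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, ...) {
  keys <- list(...)
  p <- 2147483647
  h <- (as.double(seed) %% (p - 1)) + 1
  for (k in keys) {
    kv <- if (is.character(k)) {
      cp <- utf8ToInt(k)
      sum(cp * seq_along(cp))
    } else {
      as.double(k)
    }
    h <- (h * 48271 + kv + 11) %% p
    if (h == 0) h <- 1
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

#' Row-wise Euclidean norms
#' @param x Numeric matrix.
#' @return Numeric vector of row norms.
#' @keywords internal
rowNorms <- function(x) sqrt(rowSums(x * x))
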