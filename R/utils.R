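#' Spectral radius of a square matrix
#'
#' Largest eigenvalue modulus; a VAR(1) with coupling matrix `A` is
#' stationary iff `spectralRadius(A) < 1`.
#'
#' @param A square numeric matrix.
#' @return Non-negative numeric scalar.
#' @export
spectralRadius <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  max(Mod(eigen(A, only.values = TRUE)$values))
}

## derive a reproducible child seed (kept below 2^31) from a base seed and a
## small integer tag, so each randomised stage draws from its own stream
childSeed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(tag) * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
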