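# Internal numerical helpers shared across modules.

#' Principal angles between two subspaces
#'
#' Computes the full vector of canonical (principal) angles between the column
#' spans of two matrices, in radians. Zero angles mean the spans coincide.
#'
#' @param U,V numeric matrices with the same number of rows; their column
#'   spans are compared. Columns need not be orthonormal.
#' @return numeric vector of length `min(ncol(U), ncol(V))`, angles in
#'   radians, ascending.
#' @examples
#' principal_angles(diag(4)[, 1:2], diag(4)[, 1:2])  # c(0, 0)
#' @export
principal_angles <- function(U, V) {
  Qu <- qr.Q(qr(as.matrix(U)))
  Qv <- qr.Q(qr(as.matrix(V)))
  s <- svd(crossprod(Qu, Qv), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, -1), 1))
}

# Orthonormalize the rows of a K x N matrix via QR of its transpose.
orthonormalize_rows <- function(W) {
  qrd <- qr(t(W))
  Q <- qr.Q(qrd)
  # fix signs so the retraction is continuous (positive diagonal of R)
  d <- sign(diag(qr.R(qrd)))
  d[d == 0] <- 1
  t(Q %*% diag(d, nrow = length(d)))
}

# Random row-orthonormal K x N matrix (uses the current RNG state).
random_orthonormal_rows <- function(k, n) {
  orthonormalize_rows(matrix(stats::rnorm(k * n), k, n))
}

# Population variance: mean squared deviation from the mean (divisor n, not
# n - 1). Ratio statistics in this package use population moments so that
# exact-invariance boundary cases land exactly on their nominal value.
pop_var <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}

# Derive a substream seed below 2^31 from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  (as.integer(seed) + 7919L * as.integer(stream)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so that library calls never perturb user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
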