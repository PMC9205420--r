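# Internal helpers shared across modules.

# Run code under a fixed RNG state, restoring the caller's state afterwards.
withSeed <- function(seed, code) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a scalar 'seed' is required for reproducibility", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Companion matrix of a d x d x p coefficient tensor: the top block row holds
# [A1 ... Ap], the sub-diagonal an identity shift.
companionMatrix <- function(A) {
  d <- dim(A)[1L]
  p <- dim(A)[3L]
  M <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) M[seq_len(d), (k - 1L) * d + seq_len(d)] <- A[, , k]
  if (p > 1L)
    M[d + seq_len(d * (p - 1L)), seq_len(d * (p - 1L))] <-
      diag(d * (p - 1L))
  M
}

#' Spectral radius of the companion form of a coefficient tensor
#'
#' A tv-MVAR segment with constant coefficients is stable (non-explosive)
#' exactly when the spectral radius of its companion matrix is below 1.
#'
#' @param A a \code{d x d x p} coefficient tensor (receiver x sender x lag).
#' @return the largest eigenvalue modulus of the companion matrix.
#' @export
spectralRadius <- function(A) {
  max(Mod(eigen(companionMatrix(A), only.values = TRUE)$values))
}

# Column index in the lag-stacked design for sender j at lag k (lag-major
# blocks of channels).
lagColumn <- function(j, k, d) (k - 1L) * d + j

# Indices of off-diagonal entries of a d x d matrix, in column-major order.
offDiagonal <- function(d) which(diag(d) == 0)

assertScalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite scalar in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
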