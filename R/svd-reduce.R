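#' Thin SVD of a GEM
#'
#' Decomposes the samples x transcripts matrix as \code{X = U diag(S) Vt}.
#' A deterministic sign convention is applied so results are reproducible
#' across linear-algebra backends: the largest-magnitude component of each
#' row of Vt is made positive (the matching column of U flips with it).
#'
#' @param gem a [GEM-class] or a plain numeric matrix (samples x features).
#' @return An [SVDFactors-class].
#' @examples
#' f <- svdDecompose(matrix(c(3, 4, 0, 5), 2, 2))
#' singularValues(f)   # sqrt(45), sqrt(5)
#' @export
svdDecompose <- function(gem) {
  x <- if (is(gem, "GEM")) exprValues(gem) else as.matrix(gem)
  if (length(x) == 0L) stop("empty matrix")
  if (any(!is.finite(x))) stop("matrix must be finite")
  s <- svd(x)
  Vt <- t(s$v)
  rownames(s$u) <- rownames(x)
  colnames(Vt) <- colnames(x)
  for (l in seq_along(s$d)) {
    j <- which.max(abs(Vt[l, ]))
    if (Vt[l, j] < 0) {
      Vt[l, ] <- -Vt[l, ]
      s$u[, l] <- -s$u[, l]
    }
  }
  new("SVDFactors", U = s$u, S = s$d, Vt = Vt,
      frobNorm = sqrt(sum(s$d^2)))
}

#' @describeIn svdDecompose singular values, non-increasing
#' @param f an [SVDFactors-class]
#' @export
singularValues <- function(f) f@S

#' @describeIn svdDecompose right singular vectors as rows (r x transcripts)
#' @export
rightVectors <- function(f) f@Vt

#' @describeIn svdDecompose left singular vectors (samples x r)
#' @export
leftVectors <- function(f) f@U

#' Frobenius error of rank-N truncation
#'
#' The square root of the sum of squares of the left-out singular values,
#' which equals the Frobenius norm of the difference between the matrix and
#' its rank-N approximation exactly.
#'
#' @param f an [SVDFactors-class].
#' @param N truncation rank, \code{0 <= N <= r}.
#' @return non-negative scalar.
#' @export
truncationError <- function(f, N) {
  r <- length(f@S)
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 0 || N > r)
    stop(sprintf("N must be an integer in [0, %d]", r))
  if (N == r) return(0)
  sqrt(sum(f@S[(N + 1):r]^2))
}

#' Smallest rank achieving a relative reconstruction error
#'
#' Returns the smallest N whose truncation error, relative to the full
#' Frobenius norm, is below \code{rel} -- the criterion used to pick the
#' working dimensionality before DQC evolution (e.g. \code{rel = 0.015} for
#' reconstruction to better than the 1.5\% level).
#'
#' @param f an [SVDFactors-class].
#' @param rel relative error bound in (0, 1).
#' @return integer rank.
#' @export
rankForRelativeError <- function(f, rel) {
  assertScalar(rel, "rel", 0, 1, openLower = TRUE, openUpper = TRUE)
  if (f@frobNorm == 0) return(0L)
  tail2 <- rev(cumsum(rev(f@S^2)))                 # tail2[N+1] = sum_{l>N} S^2
  errs <- sqrt(c(tail2, 0))
  which(errs / f@frobNorm < rel)[1L] - 1L
}

#' Reduced sample coordinates for DQC
#'
#' The first N columns of U, not scaled by the singular values; these
#' orthonormal coordinates are the input points for DQC evolution.
#'
#' @param f an [SVDFactors-class].
#' @param N number of dimensions, \code{N <= r}.
#' @return samples x N matrix.
#' @export
reducedCoordinates <- function(f, N) {
  r <- length(f@S)
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 1 || N > r)
    stop(sprintf("N must be an integer in [1, %d]", r))
  f@U[, seq_len(N), drop = FALSE]
}
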