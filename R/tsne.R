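# Exact-gradient t-SNE, sized for ensembles over a few hundred samples.
# Input affinities are computed once per data set and shared by every
# randomly initialized layout in an ensemble.

# Symmetrized input affinities P at the requested perplexity (entropy
# bisection on the per-point Gaussian precision, 50 iterations).
tsneAffinities <- function(X, perplexity = 30) {
  n <- nrow(X)
  if (perplexity >= n / 3)
    stop(sprintf("perplexity %g too large for %d samples (needs < n/3)",
                 perplexity, n))
  D2 <- crossDist2(X, X)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    for (iter in seq_len(50L)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { H <- 0 } else {
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / max(sum(w), 1e-300)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Gradient-descent layout from a given affinity matrix; deterministic for a
# given seed.  Early exaggeration x12 for the first third of the schedule,
# adaptive gains, momentum 0.5 then 0.8.
tsneLayout <- function(P, dims = 2, seed = 1L, nIter = 300L) {
  n <- nrow(P)
  eeIter <- floor(nIter / 3)
  eta <- max(n / 48, 50)
  Y <- withSeed(seed, matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims))
  inc <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  Pee <- P * 12
  for (iter in seq_len(nIter)) {
    Pit <- if (iter <= eeIter) Pee else P
    qnum <- 1 / (1 + crossDist2(Y, Y))
    diag(qnum) <- 0
    Q <- pmax(qnum / sum(qnum), 1e-12)
    L <- (Pit - Q) * qnum
    grad <- 4 * (rowSums(L) * Y - L %*% Y)
    momentum <- if (iter <= eeIter) 0.5 else 0.8
    flip <- sign(grad) != sign(inc)
    gains <- pmax(ifelse(flip, gains + 0.2, gains * 0.8), 0.01)
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
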