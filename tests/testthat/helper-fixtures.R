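# Shared fixtures and small independent oracles used across the suite.

# A minimal GEM built by hand.
tinyGem <- function(values = matrix(c(5, 2, 3, 4, 1, 2), nrow = 2, byrow = TRUE),
                    samples = paste0("S", seq_len(nrow(values))),
                    transcripts = paste0("t", seq_len(ncol(values)))) {
  dimnames(values) <- list(samples, transcripts)
  GEM(values)
}

# Small synthetic study shared by the recovery tests.
defaultSim <- function(seed) generateGem(synthConfig(seed = seed))

# Wrap a plain coordinate matrix as a single-frame trajectory.
asTrajectory <- function(X, sigma = 1) {
  new("Trajectory", frames = list(X), sigma = sigma, mass = 1, dt = 0.1)
}

# Two-sample Welch t statistic, written out directly.
welchT <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# One-way F statistic across groups, written out directly.
oneWayF <- function(x, g) {
  g <- as.factor(g)
  n <- length(x); k <- nlevels(g)
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Two-sample Kolmogorov-Smirnov statistic by an explicit ECDF sweep.
ksStatOracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1L))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1L))
  max(abs(Fx - Fy))
}

# Mean silhouette width from raw pairwise distances.
silhouetteOracle <- function(X, labels) {
  d <- as.matrix(dist(X))
  s <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1L)))
    (b - a) / max(a, b)
  }, numeric(1L))
  mean(s)
}

# Chi-squared statistic of a 2x2 table from first principles.
chisqOracle <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Hypergeometric upper tail by direct binomial-coefficient summation.
hyperTailOracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

skipIfNot <- function(pkg) testthat::skip_if_not_installed(pkg)
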