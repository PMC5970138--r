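test_that("a single Gaussian yields the harmonic potential", {
  pts <- matrix(0)
  expect_equal(dqcPotential(pts, 1, matrix(0)), 0)
  expect_equal(dqcPotential(pts, 1, matrix(2)), 2)
  expect_equal(dqcPotential(pts, 2, matrix(c(1, 3), ncol = 1)),
               c(1, 9) / (2 * 4))
})

test_that("the potential is symmetric for mirror-symmetric data", {
  pts <- matrix(c(-1.2, 1.2), ncol = 1)
  xs <- matrix(seq(-3, 3, by = 0.3), ncol = 1)
  expect_equal(dqcPotential(pts, 0.7, xs), rev(dqcPotential(pts, 0.7, -xs)))
})

test_that("the analytic potential matches a finite-difference Laplacian", {
  pts <- withr::with_seed(7, matrix(rnorm(24), 12, 2))
  sigma <- 0.8
  h <- 1e-4
  phi <- function(q) sum(exp(-colSums((t(pts) - q)^2) / (2 * sigma^2)))
  v0fd <- function(q) {
    lap <- 0
    for (k in 1:2) {
      e <- c(0, 0); e[k] <- h
      lap <- lap + (phi(q + e) - 2 * phi(q) + phi(q - e)) / h^2
    }
    sigma^2 / 2 * lap / phi(q)
  }
  e0fd <- -min(apply(pts, 1, v0fd))
  qs <- withr::with_seed(8, matrix(rnorm(10), 5, 2))
  expect_equal(dqcPotential(pts, sigma, qs),
               apply(qs, 1, v0fd) + e0fd, tolerance = 1e-5)
})

test_that("potential underflow far from all data raises a sigma hint", {
  expect_error(dqcPotential(matrix(0), 0.1, matrix(100)), "sigma")
})

test_that("operator matrices have the expected structure in limiting cases", {
  # coincident points: all-ones overlap, one surviving basis state
  ops <- buildOperators(matrix(0, 2, 1), dqcConfig(sigma = 1, mass = 1))
  expect_equal(ops@overlap, matrix(1, 2, 2))
  expect_equal(ncol(ops@basis), 1L)
  # far-separated points: overlap ~ identity, H ~ diagonal
  far <- matrix(c(0, 100, 200), ncol = 1)
  ops <- buildOperators(far, dqcConfig(sigma = 1, mass = 1))
  expect_equal(ops@overlap, diag(3), tolerance = 1e-10)
  offdiag <- ops@H - diag(diag(ops@H))
  expect_lt(max(abs(offdiag)), 1e-8 * max(abs(diag(ops@H))))
  expect_error(buildOperators(matrix(numeric(0), 0, 1)), "at least one")
})

test_that("the ground state energy matches a dense-grid 1-D Hamiltonian", {
  # points dense relative to sigma so the 5-Gaussian variational basis can
  # represent the ground state of the single data-derived well
  pts <- matrix(seq(-0.5, 0.5, by = 0.25), ncol = 1)
  sigma <- 0.4
  mass <- 1
  ops <- buildOperators(pts, dqcConfig(sigma = sigma, mass = mass))
  eBasis <- sort(eigen(ops@H, symmetric = TRUE, only.values = TRUE)$values)
  # independent oracle: central-difference discretization of -(1/2m) d2/dx2 + V
  ng <- 1024L
  xg <- seq(-6, 6, length.out = ng)
  hg <- xg[2] - xg[1]
  Vg <- dqcPotential(pts, sigma, matrix(xg, ncol = 1))
  Hg <- diag(1 / (mass * hg^2) + Vg)
  Hg[cbind(1:(ng - 1), 2:ng)] <- Hg[cbind(2:ng, 1:(ng - 1))] <-
    -1 / (2 * mass * hg^2)
  eGrid <- sort(eigen(Hg, symmetric = TRUE, only.values = TRUE)$values)
  gap <- eGrid[2] - eGrid[1]
  expect_lt(abs(eBasis[1] - eGrid[1]), 0.02 * gap)
})

test_that("a single packet stays at the potential minimum", {
  tr <- dqcEvolve(matrix(c(0.5, -0.2), 1, 2),
                  dqcConfig(sigma = 1, mass = 1, nFrames = 10))
  drift <- max(abs(frameCoords(tr, 11) - frameCoords(tr, 1)))
  expect_lt(drift, 1e-6)
})

test_that("evolution contracts clusters without moving their centers", {
  set.seed(11)
  sigma <- 0.3
  P <- rbind(matrix(rnorm(20, 0, 0.4), 10, 2),
             matrix(rnorm(20, 0, 0.4) + 3, 10, 2))   # centers 10 sigma apart
  tr <- dqcEvolve(P, dqcConfig(sigma = sigma, dt = 2, nFrames = 20))
  within0 <- mean(c(dist(frameCoords(tr, 1)[1:10, ]),
                    dist(frameCoords(tr, 1)[11:20, ])))
  within1 <- mean(c(dist(frameCoords(tr, 21)[1:10, ]),
                    dist(frameCoords(tr, 21)[11:20, ])))
  between <- function(X) sqrt(sum((colMeans(X[1:10, ]) - colMeans(X[11:20, ]))^2))
  expect_lt(within1, 0.5 * within0)
  expect_lt(abs(between(frameCoords(tr, 21)) - between(P)) / between(P), 0.2)
})

test_that("mirror-symmetric input evolves mirror-symmetrically", {
  base <- matrix(c(0.4, 0.9, 1.6, 0.1, -0.5, 0.3), 3, 2)
  P <- rbind(base, -base)
  tr <- dqcEvolve(P, dqcConfig(sigma = 0.8, mass = 1, nFrames = 8))
  for (fr in c(2, 5, 9)) {
    X <- frameCoords(tr, fr)
    expect_equal(X[1:3, ], -X[4:6, ], tolerance = 1e-6)
  }
})

test_that("evolution is unitary and conserves energy within frames", {
  set.seed(3)
  P <- matrix(rnorm(30), 15, 2)
  tr <- dqcEvolve(P, dqcConfig(sigma = 0.5, nFrames = 10, stepsPerFrame = 3))
  expect_lt(max(tr@normDrift), 1e-8)
  expect_lt(max(tr@energyDrift), 1e-6)
})

test_that("rescaling points and sigma together rescales the trajectory", {
  set.seed(5)
  P <- matrix(rnorm(24), 12, 2)
  lambda <- 3.7
  cfg1 <- dqcConfig(sigma = 0.6, mass = 2 / 0.6^2, nFrames = 6)
  cfg2 <- dqcConfig(sigma = 0.6 * lambda, mass = 2 / (0.6 * lambda)^2, nFrames = 6)
  tr1 <- dqcEvolve(P, cfg1)
  tr2 <- dqcEvolve(P * lambda, cfg2)
  for (fr in c(2, 7))
    expect_equal(frameCoords(tr2, fr), frameCoords(tr1, fr) * lambda,
                 tolerance = 1e-8)
})

test_that("the automatic mass default preserves scale equivariance", {
  set.seed(6)
  P <- matrix(rnorm(20), 10, 2)
  tr1 <- dqcEvolve(P, dqcConfig(nFrames = 4))
  tr2 <- dqcEvolve(P * 10, dqcConfig(nFrames = 4))
  expect_equal(frameCoords(tr2, 5), frameCoords(tr1, 5) * 10, tolerance = 1e-8)
})

test_that("frame segmentation recovers blobs and validates k", {
  set.seed(9)
  X <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2), matrix(rnorm(30, 5, 0.2), 15, 2))
  tr <- asTrajectory(X)
  expect_equal(segmentFrame(tr, 1, 1), rep(1L, 30))
  lab <- segmentFrame(tr, 1, 2, seed = 2)
  expect_equal(length(unique(lab[1:15])), 1L)
  expect_equal(length(unique(lab[16:30])), 1L)
  expect_false(lab[1] == lab[16])
  expect_error(segmentFrame(tr, 1, 31), "exceeds")
})

test_that("segmenting an arch gives contiguous segments along arc length", {
  theta <- seq(0, pi, length.out = 120)
  arch <- cbind(cos(theta), sin(theta)) +
    withr::with_seed(10, matrix(rnorm(240, 0, 0.01), 120, 2))
  lab <- segmentFrame(asTrajectory(arch), 1, 7, seed = 3)
  # walking along the curve, the label changes exactly k-1 = 6 times
  expect_equal(sum(diff(lab) != 0), 6L)
})

test_that("separating dimensions are found by the largest-gap score", {
  X <- cbind(c(0, 0.01, 0.02, 1.0, 1.01),      # strongly bimodal
             rep(0.5, 5),                       # constant
             c(0.1, 0.3, 0.5, 0.7, 0.9))        # evenly spread
  sel <- separatingDimensions(asTrajectory(X), 1, minScore = 0.5)
  expect_equal(as.integer(sel), 1L)
  expect_equal(attr(sel, "scores")[2], 0)
  allConst <- matrix(1, 5, 3)
  expect_length(separatingDimensions(asTrajectory(allConst), 1), 0)
})

test_that("evolution of reduced synthetic coordinates recovers planted classes", {
  skipIfNot("mclust")
  for (seed in 1:10) {
    sim <- defaultSim(seed)
    gem <- quantileNormalize(sim$gem)
    co <- reducedCoordinates(svdDecompose(gem), 12)
    tr <- dqcEvolve(co, dqcConfig())
    labs <- trajectoryClusters(tr)
    expect_gte(mclust::adjustedRandIndex(labs, sim$truth$classLabels), 0.9)
  }
})

test_that("subsampled-basis evolution tracks the exact-basis trajectory", {
  set.seed(13)
  P <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 4, 0.3), 20, 2))
  exact <- dqcEvolve(P, dqcConfig(sigma = 0.5, nFrames = 10))
  sub <- dqcEvolve(P, dqcConfig(sigma = 0.5, nFrames = 10,
                                maxExactPoints = 25, seed = 2))
  labsE <- trajectoryClusters(exact)
  labsS <- trajectoryClusters(sub)
  skipIfNot("mclust")
  expect_equal(mclust::adjustedRandIndex(labsE, labsS), 1)
  expect_equal(labsE, rep(1:2, each = 20), ignore_attr = TRUE)
})

test_that("uniform-random dimensions rarely reach the separation cutoff", {
  # null distribution of the gap score for structureless 1-D data: a few
  # percent of draws graze the 0.5 default cutoff, none approach the
  # near-1 scores of genuinely bimodal dimensions
  scores <- vapply(1:100, function(s) {
    X <- withr::with_seed(s, matrix(runif(200), ncol = 1))
    attr(separatingDimensions(asTrajectory(X), 1), "scores")[1]
  }, numeric(1L))
  expect_gte(sum(scores < 0.5), 95L)
  expect_true(all(scores < 0.65))
})
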