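#' DQC evolution parameters
#'
#' @slot sigma Gaussian width in reduced-coordinate units; \code{NA} means
#'   automatic, 2.2 times the median nearest-neighbor distance of the input
#'   points.
#' @slot mass mass parameter of the Hamiltonian \code{H = -(1/2m) Lap + V};
#'   \code{NA} means \code{3 / sigma^2} (mass 3 in sigma units).  A low
#'   mass exploits quantum tunneling so packets are not trapped by small
#'   density fluctuations; very low masses delocalize packets across
#'   genuinely separate basins.
#' @slot dt evolution time step.
#' @slot nFrames number of evolved frames to produce.
#' @slot stepsPerFrame evolution steps applied between recorded frames.
#' @slot basisTol relative overlap-eigenvalue cutoff for truncating the
#'   Gaussian basis (guards near-duplicate points).
#' @slot maxExactPoints above this point count the operator basis is built
#'   on a seeded subsample and the remaining packets are evolved in that
#'   fixed basis.
#' @slot seed integer seed (used only for the optional subsampling).
#' @export
setClass("DQCConfig",
         representation(sigma = "numeric", mass = "numeric", dt = "numeric",
                        nFrames = "integer", stepsPerFrame = "integer",
                        basisTol = "numeric", maxExactPoints = "integer",
                        seed = "integer"))

setValidity("DQCConfig", function(object) {
  if (!is.na(object@sigma) && object@sigma <= 0) return("sigma must be > 0")
  if (!is.na(object@mass) && object@mass <= 0) return("mass must be > 0")
  if (object@dt <= 0) return("dt must be > 0")
  if (object@nFrames < 1L || object@stepsPerFrame < 1L)
    return("nFrames and stepsPerFrame must be >= 1")
  if (object@basisTol <= 0 || object@basisTol >= 1)
    return("basisTol must be in (0, 1)")
  TRUE
})

#' Create a DQC configuration
#'
#' @param sigma,mass,dt,nFrames,stepsPerFrame,basisTol,maxExactPoints,seed
#'   see the slot documentation of [DQCConfig-class].
#' @return a validated [DQCConfig-class].
#' @export
dqcConfig <- function(sigma = NA_real_, mass = NA_real_, dt = 0.1,
                      nFrames = 60, stepsPerFrame = 1, basisTol = 1e-6,
                      maxExactPoints = 2000, seed = 1L) {
  new("DQCConfig", sigma = as.numeric(sigma), mass = as.numeric(mass),
      dt = as.numeric(dt), nFrames = as.integer(nFrames),
      stepsPerFrame = as.integer(stepsPerFrame),
      basisTol = as.numeric(basisTol),
      maxExactPoints = as.integer(maxExactPoints), seed = as.integer(seed))
}

#' DQC operator matrices in the truncated Gaussian basis
#'
#' @slot overlap Gaussian overlap matrix of the basis points.
#' @slot H Hamiltonian in the truncated orthonormal basis.
#' @slot X list of position-operator matrices, one per dimension.
#' @slot basis basis-point x truncated-basis transformation (columns are
#'   orthonormal combinations of the point Gaussians).
#' @slot E0 constant potential offset making min V over the data zero.
#' @slot sigma,mass parameters actually used.
#' @slot basisIdx indices of the points whose Gaussians span the basis.
#' @export
setClass("DQCOperators",
         representation(overlap = "matrix", H = "matrix", X = "list",
                        basis = "matrix", E0 = "numeric", sigma = "numeric",
                        mass = "numeric", basisIdx = "integer"))

setValidity("DQCOperators", function(object) {
  S <- object@overlap
  if (max(abs(S - t(S))) > 1e-8) return("overlap not symmetric")
  if (max(abs(diag(S) - 1)) > 1e-12) return("overlap diagonal must be 1")
  if (max(abs(object@H - t(object@H))) > 1e-8) return("H not Hermitian")
  for (Xk in object@X)
    if (max(abs(Xk - t(Xk))) > 1e-8) return("X_k not Hermitian")
  TRUE
})

#' @export
setMethod("show", "DQCOperators", function(object) {
  cat(sprintf("DQCOperators: %d basis Gaussians -> %d orthonormal states, %d dims (sigma=%.4g, mass=%.4g)\n",
              nrow(object@overlap), ncol(object@basis), length(object@X),
              object@sigma, object@mass))
})

# Median nearest-neighbor distance; the automatic sigma.
medianNNDistance <- function(points) {
  d2 <- crossDist2(points, points)
  diag(d2) <- Inf
  nn <- sqrt(apply(d2, 1L, min))
  s <- stats::median(nn)
  if (s == 0) s <- stats::median(nn[nn > 0])
  if (!is.finite(s) || s == 0) stop("all points coincide; sigma cannot be inferred")
  s
}

# Automatic parameters: sigma is 2.2x the median nearest-neighbor distance
# (the median NN distance itself underestimates a useful Parzen bandwidth in
# more than a few dimensions); mass is 3 in units where sigma = 1, i.e.
# 3 / sigma^2, which balances the kinetic term against the potential (both
# O(d)) and keeps the dynamics invariant under joint rescaling of points
# and sigma.  Low masses tunnel through small density fluctuations; much
# lower values delocalize packets across genuinely separate basins.
resolveDqcParams <- function(points, config) {
  sigma <- if (is.na(config@sigma)) 2.2 * medianNNDistance(points) else config@sigma
  mass <- if (is.na(config@mass)) 3 / sigma^2 else config@mass
  list(sigma = sigma, mass = mass)
}

#' The data-derived quantum potential
#'
#' The Parzen sum of sample-centered Gaussians, \code{phi(x) = sum_i
#' exp(-||x - x_i||^2 / (2 sigma^2))}, is a proxy for the data density; the
#' potential whose ground state is that density estimate is
#' \code{V(x) = E0 + (sigma^2/2) * Lap(phi)/phi}, with \code{E0} fixed so
#' the minimum of V over the data points is zero.  Local minima of V mark
#' regions of high data density.
#'
#' @param points samples x d matrix of Gaussian centers.
#' @param sigma Gaussian width, > 0.
#' @param x query location: a length-d vector or an m x d matrix.
#' @return numeric vector of potential values, one per query row.
#' @examples
#' dqcPotential(matrix(0), sigma = 1, x = matrix(2))  # harmonic: 2^2/2 = 2
#' @export
dqcPotential <- function(points, sigma, x) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("need at least one point")
  assertScalar(sigma, "sigma", 0, Inf, openLower = TRUE)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(points)) stop("query dimension mismatch")
  rawPotential(points, sigma, x) + potentialOffset(points, sigma)
}

# Unshifted (sigma^2/2) Lap(phi)/phi, evaluated analytically.
rawPotential <- function(points, sigma, q) {
  r2 <- crossDist2(q, points)
  w <- exp(-r2 / (2 * sigma^2))
  phi <- rowSums(w)
  if (any(phi < 1e-290))
    stop("Parzen sum underflows at a query point; increase sigma")
  rowSums(w * r2) / (2 * sigma^2 * phi) - ncol(points) / 2
}

# E0: constant shift making min over the data points of V zero.
potentialOffset <- function(points, sigma) {
  -min(rawPotential(points, sigma, points))
}

#' Build DQC operator matrices
#'
#' Constructs the Gaussian overlap matrix, the truncated orthonormal basis,
#' and the Hamiltonian and position operators projected into that basis.
#' Kinetic matrix elements are analytic for Gaussians; potential matrix
#' elements use the midpoint approximation \code{<i|V|j> = overlap_ij *
#' V((x_i + x_j)/2)}, exact in the coincident-point limit.
#'
#' @param points samples x d matrix (all points; they define the density).
#' @param config a [DQCConfig-class].
#' @param basisIdx optional indices of the points whose Gaussians span the
#'   operator basis (defaults to all points, or a seeded subsample when
#'   there are more than \code{maxExactPoints}).
#' @return a [DQCOperators-class].
#' @export
buildOperators <- function(points, config = dqcConfig(), basisIdx = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  if (n < 1L) stop("need at least one point")
  pars <- resolveDqcParams(points, config)
  sigma <- pars$sigma; mass <- pars$mass
  if (is.null(basisIdx)) {
    basisIdx <- if (n > config@maxExactPoints)
      sort(withSeed(config@seed, sample.int(n, config@maxExactPoints)))
    else seq_len(n)
  }
  B <- points[basisIdx, , drop = FALSE]
  nb <- nrow(B)

  D2 <- crossDist2(B, B)
  S <- exp(-D2 / (4 * sigma^2))
  eig <- eigen(S, symmetric = TRUE)
  keep <- eig$values > config@basisTol * eig$values[1L]
  if (!any(keep) || eig$values[1L] <= 0) stop("degenerate Gaussian basis")
  E <- sweep(eig$vectors[, keep, drop = FALSE], 2L,
             sqrt(eig$values[keep]), "/")

  K <- S * (d / (4 * sigma^2) - D2 / (8 * sigma^4)) / mass
  # potential elements only where the pair overlap is non-negligible; for
  # far-separated pairs overlap_ij * V(midpoint) vanishes anyway
  mid <- matrix(0, nb * nb, d)
  for (k in seq_len(d)) mid[, k] <- as.vector(outer(B[, k], B[, k], "+") / 2)
  need <- as.vector(S) > 1e-14
  Vvals <- numeric(nb * nb)
  Vvals[need] <- dqcPotential(points, sigma, mid[need, , drop = FALSE])
  Vm <- S * matrix(Vvals, nb, nb)
  project <- function(M) {
    P <- crossprod(E, M %*% E)
    (P + t(P)) / 2
  }
  Xops <- lapply(seq_len(d), function(k)
    project(S * (outer(B[, k], B[, k], "+") / 2)))
  new("DQCOperators", overlap = S, H = project(K + Vm), X = Xops,
      basis = E, E0 = potentialOffset(points, sigma), sigma = sigma,
      mass = mass, basisIdx = as.integer(basisIdx))
}

# Coefficients of Gaussians centered at `pts` in the truncated basis of `ops`,
# built from basis centers `B`; columns are normalized states.
gaussianStates <- function(ops, B, pts) {
  Sc <- exp(-crossDist2(B, pts) / (4 * ops@sigma^2))
  C <- crossprod(ops@basis, Sc)
  nrm <- sqrt(colSums(C^2))
  if (any(nrm < 1e-12)) stop("a point's Gaussian is orthogonal to the truncated basis")
  sweep(C, 2L, nrm, "/")
}

#' Evolve sample packets under the data Hamiltonian
#'
#' Each sample's Gaussian is propagated with \code{exp(-i dt H)}; after
#' every recorded frame the packets are re-centered at their new position
#' expectations and the operators rebuilt, so points iteratively flow into
#' the minima of the quantum potential (the dense regions of the data).
#'
#' @param points samples x d matrix, typically [reducedCoordinates()].
#' @param config a [DQCConfig-class].
#' @return a [Trajectory-class] whose first frame is the input.
#' @export
dqcEvolve <- function(points, config = dqcConfig()) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n < 1L) stop("need at least one point")
  pars <- resolveDqcParams(points, config)
  cfg <- config
  cfg@sigma <- pars$sigma; cfg@mass <- pars$mass

  frames <- vector("list", cfg@nFrames + 1L)
  frames[[1L]] <- points
  normDrift <- energyDrift <- numeric(cfg@nFrames)
  cur <- points
  basisIdx <- if (n > cfg@maxExactPoints)
    sort(withSeed(cfg@seed, sample.int(n, cfg@maxExactPoints))) else seq_len(n)

  for (fr in seq_len(cfg@nFrames)) {
    ops <- buildOperators(cur, cfg, basisIdx = basisIdx)
    B <- cur[basisIdx, , drop = FALSE]
    C <- gaussianStates(ops, B, cur)
    eig <- eigen(ops@H, symmetric = TRUE)
    phase <- exp(-1i * cfg@dt * eig$values)
    Psi <- eig$vectors %*% ((t(eig$vectors) %*% C) + 0i)
    # track unitarity/energy step by step within the frame
    coef0 <- t(eig$vectors) %*% C + 0i
    nrm0 <- Re(colSums(Conj(coef0) * coef0))
    en0 <- Re(colSums(Conj(coef0) * (eig$values * coef0))) / nrm0
    coef <- coef0
    nd <- ed <- 0
    for (s in seq_len(cfg@stepsPerFrame)) {
      coef <- phase * coef
      nrm <- Re(colSums(Conj(coef) * coef))
      en <- Re(colSums(Conj(coef) * (eig$values * coef))) / nrm
      nd <- max(nd, max(abs(nrm - nrm0)))
      ed <- max(ed, max(abs(en - en0)))
    }
    normDrift[fr] <- nd
    energyDrift[fr] <- ed
    Psi <- eig$vectors %*% coef
    nrm <- Re(colSums(Conj(Psi) * Psi))
    nxt <- matrix(0, n, d)
    for (k in seq_len(d))
      nxt[, k] <- Re(colSums(Conj(Psi) * (ops@X[[k]] %*% Psi))) / nrm
    if (any(!is.finite(nxt)))
      stop(sprintf("non-finite coordinates at frame %d", fr))
    frames[[fr + 1L]] <- nxt
    cur <- nxt
  }
  new("Trajectory", frames = frames, sigma = cfg@sigma, mass = cfg@mass,
      dt = cfg@dt, normDrift = normDrift, energyDrift = energyDrift)
}

#' k-means segmentation of one trajectory frame
#'
#' Used to cut extended structures (such as the glioma "arch") that DQC
#' evolution reveals into ordered groups.
#'
#' @param traj a [Trajectory-class].
#' @param frame 1-based frame index (frame 1 = input coordinates).
#' @param k number of segments.
#' @param seed seed for the k-means++-style restarts (50 restarts, best
#'   inertia kept).
#' @return integer vector of segment labels.
#' @export
segmentFrame <- function(traj, frame, k, seed = 1L) {
  coords <- frameCoords(traj, frame)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(coords)) stop("k exceeds the number of points")
  if (k == 1L) return(rep(1L, nrow(coords)))
  withSeed(seed,
           stats::kmeans(coords, centers = k, nstart = 50L,
                         iter.max = 100L)$cluster)
}

#' Dimensions along which the evolved data clearly separates
#'
#' For each dimension the sorted 1-D coordinates are split at their largest
#' gap; the separation score is \code{1 - max(side range)/total range}.  A
#' bimodal dimension whose modes are tight relative to their separation
#' scores near 1; a constant dimension scores 0 and is never selected.
#'
#' @param traj a [Trajectory-class].
#' @param frame 1-based frame index.
#' @param minScore minimum score for a dimension to be reported.
#' @return integer vector of dimension indices sorted by decreasing score,
#'   with the scores of all dimensions attached as attribute
#'   \code{"scores"}.
#' @export
separatingDimensions <- function(traj, frame, minScore = 0.5) {
  coords <- frameCoords(traj, frame)
  scores <- apply(coords, 2L, function(x) {
    s <- sort(x)
    n <- length(s)
    total <- s[n] - s[1L]
    if (total <= 0 || n < 2L) return(0)
    g <- which.max(diff(s))
    1 - max(s[g] - s[1L], s[n] - s[g + 1L]) / total
  })
  sel <- which(scores >= minScore)
  sel <- sel[order(scores[sel], decreasing = TRUE)]
  attr(sel, "scores") <- scores
  sel
}

#' Cluster labels from a trajectory frame by single linkage
#'
#' After DQC evolution, points belonging to one basin have collapsed to
#' within a few widths of each other; single-linkage clustering at
#' threshold \code{h} (default: the evolution's sigma) reads the clusters
#' off the final frame.
#'
#' @param traj a [Trajectory-class].
#' @param frame frame index, default the last.
#' @param h merge-height threshold.
#' @return integer cluster labels.
#' @export
trajectoryClusters <- function(traj, frame = nFrames(traj), h = traj@sigma) {
  coords <- frameCoords(traj, frame)
  if (nrow(coords) == 1L) return(1L)
  hc <- stats::hclust(stats::dist(coords), method = "single")
  stats::cutree(hc, h = h)
}
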