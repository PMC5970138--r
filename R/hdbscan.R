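# Hierarchical density-based clustering (HDBSCAN): mutual-reachability
# single-linkage hierarchy, condensed by minimum cluster size, with
# excess-of-mass cluster selection.  Noise points are labeled -1.

#' Density-based cluster labels for a point set
#'
#' @param X points x dims coordinate matrix (e.g. one t-SNE embedding).
#' @param minClusterSize smallest cluster size considered real.
#' @param minSamples neighbor count for the core distance (defaults to
#'   \code{minClusterSize}).
#' @param allowSingleCluster if TRUE (default) the hierarchy root may be
#'   selected, so a data set forming one coherent blob yields one cluster
#'   rather than all-noise.
#' @return integer labels, 1..k for clusters and -1 for noise.
#' @export
hdbscanLabels <- function(X, minClusterSize = 5, minSamples = minClusterSize,
                          allowSingleCluster = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  mcs <- max(2L, as.integer(minClusterSize))
  if (n < 2L) return(rep(1L, n))
  if (n <= mcs) return(rep(if (allowSingleCluster) 1L else -1L, n))

  d <- sqrt(crossDist2(X, X))
  k <- min(as.integer(minSamples), n - 1L)
  # core distance: distance to the k-th nearest other point
  core <- vapply(seq_len(n), function(i) sort(d[i, -i], partial = k)[k],
                 numeric(1L))
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0

  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  condensedLabels(hc, n, mcs, allowSingleCluster)
}

# Walk the single-linkage tree top-down, keep only components of size >=
# mcs as clusters, score them by stability sum(lambda_point - lambda_birth),
# and select clusters by excess of mass.
condensedLabels <- function(hc, n, mcs, allowSingleCluster) {
  m <- n - 1L
  merge <- hc$merge
  lambdaAt <- 1 / pmax(hc$height, .Machine$double.xmin)

  ptsUnder <- vector("list", m)              # points below each linkage node
  sizes <- integer(m)
  for (i in seq_len(m)) {
    kids <- merge[i, ]
    p <- integer(0)
    for (c in kids) p <- c(p, if (c < 0) -c else ptsUnder[[c]])
    ptsUnder[[i]] <- p
    sizes[i] <- length(p)
  }

  nodeCluster <- integer(m)                  # condensed cluster owning a node
  nodeCluster[m] <- 1L
  birth <- c(0)                              # per-cluster birth lambda
  parent <- c(0L)                            # per-cluster parent cluster
  stability <- c(0)
  pointCluster <- integer(n)
  nodeSize <- function(c) if (c < 0) 1L else sizes[c]

  for (i in m:1) {
    C <- nodeCluster[i]
    if (C == 0L) next                        # subtree already emptied
    lam <- lambdaAt[i]
    kids <- merge[i, ]
    s1 <- nodeSize(kids[1L]); s2 <- nodeSize(kids[2L])
    big <- c(s1, s2) >= mcs
    if (all(big)) {                          # true split: two new clusters
      stability[C] <- stability[C] + (s1 + s2) * (lam - birth[C])
      for (c in kids) {
        newId <- length(birth) + 1L
        birth[newId] <- lam
        parent[newId] <- C
        stability[newId] <- 0
        if (c < 0) pointCluster[-c] <- newId else nodeCluster[c] <- newId
      }
    } else if (any(big)) {                   # small side falls out as points
      keep <- kids[big][1L]; drop <- kids[!big][1L]
      dropPts <- if (drop < 0) -drop else ptsUnder[[drop]]
      stability[C] <- stability[C] + length(dropPts) * (lam - birth[C])
      pointCluster[dropPts] <- C
      # record the exit lambda of the dropped points
      if (drop > 0) nodeCluster[drop] <- 0L
      if (keep < 0) pointCluster[-keep] <- C else nodeCluster[keep] <- C
    } else {                                 # cluster dies: all points exit
      allPts <- ptsUnder[[i]]
      stability[C] <- stability[C] + length(allPts) * (lam - birth[C])
      pointCluster[allPts] <- C
      for (c in kids) if (c > 0) nodeCluster[c] <- 0L
    }
  }

  nc <- length(birth)
  children <- split(seq_len(nc)[-1L], parent[-1L])
  selected <- rep(FALSE, nc)
  subStab <- stability
  for (C in nc:1) {
    ch <- children[[as.character(C)]]
    if (is.null(ch) || length(ch) == 0L) {
      selected[C] <- C > 1L || allowSingleCluster
      subStab[C] <- stability[C]
    } else {
      cs <- sum(subStab[ch])
      if (stability[C] >= cs && (C > 1L || allowSingleCluster)) {
        selected[C] <- TRUE
        # deselect the whole subtree
        stack <- ch
        while (length(stack) > 0L) {
          x <- stack[[1L]]; stack <- stack[-1L]
          selected[x] <- FALSE
          xc <- children[[as.character(x)]]
          if (!is.null(xc)) stack <- c(stack, xc)
        }
        subStab[C] <- stability[C]
      } else {
        subStab[C] <- cs
      }
    }
  }

  selId <- which(selected)
  labels <- rep(-1L, n)
  if (length(selId) > 0L) {
    # a point belongs to the selected ancestor (or self) of its exit cluster
    up <- function(C) {
      while (C != 0L) {
        if (selected[C]) return(C)
        C <- parent[C]
      }
      0L
    }
    lab <- vapply(pointCluster, up, integer(1L))
    remap <- stats::setNames(seq_along(selId), selId)
    labels[lab > 0L] <- as.integer(remap[as.character(lab[lab > 0L])])
  }
  labels
}
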