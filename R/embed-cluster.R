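#' Embedding-ensemble configuration
#'
#' @slot nEmbeddings number of randomly initialized t-SNE embeddings
#'   (default 1000; reduce for quick runs -- the ensemble size is a
#'   configuration value, not a constant).
#' @slot embedDims 2 or 3.
#' @slot perplexity t-SNE perplexity (must stay below n/3).
#' @slot minClusterSize HDBSCAN minimum cluster size; \code{NA} means
#'   \code{max(5, round(n/100))}.
#' @slot nConsensusClusters consensus cluster count; \code{NA} picks the
#'   count with the largest lifetime in the co-association dendrogram.
#' @slot tsneIter gradient-descent iterations per embedding.
#' @slot logTransform log1p-transform expression values before embedding.
#' @slot seed integer; embedding e uses a sub-seed derived from
#'   \code{seed + e}, so the whole ensemble is deterministic.
#' @export
setClass("EmbedConfig",
         representation(nEmbeddings = "integer", embedDims = "integer",
                        perplexity = "numeric", minClusterSize = "integer",
                        nConsensusClusters = "integer", tsneIter = "integer",
                        logTransform = "logical", seed = "integer"))

setValidity("EmbedConfig", function(object) {
  if (object@nEmbeddings < 1L) return("nEmbeddings must be >= 1")
  if (!object@embedDims %in% c(2L, 3L)) return("embedDims must be 2 or 3")
  if (object@perplexity <= 0) return("perplexity must be > 0")
  TRUE
})

#' Create an embedding-ensemble configuration
#'
#' @param nEmbeddings,embedDims,perplexity,minClusterSize,nConsensusClusters
#'   see [EmbedConfig-class].
#' @param tsneIter,logTransform,seed see [EmbedConfig-class].
#' @return a validated [EmbedConfig-class].
#' @export
embedConfig <- function(nEmbeddings = 1000, embedDims = 2, perplexity = 30,
                        minClusterSize = NA, nConsensusClusters = NA,
                        tsneIter = 300, logTransform = TRUE, seed = 1L) {
  new("EmbedConfig", nEmbeddings = as.integer(nEmbeddings),
      embedDims = as.integer(embedDims), perplexity = as.numeric(perplexity),
      minClusterSize = as.integer(minClusterSize),
      nConsensusClusters = as.integer(nConsensusClusters),
      tsneIter = as.integer(tsneIter), logTransform = as.logical(logTransform),
      seed = as.integer(seed))
}

#' Ensemble of randomly initialized t-SNE embeddings
#'
#' Input affinities are computed once from the (optionally log1p-transformed)
#' expression values; each ensemble member then descends from its own seeded
#' random initialization.  Identical configurations give identical
#' ensembles.
#'
#' @param gem a [GEM-class] (or samples x features matrix).
#' @param config an [EmbedConfig-class].
#' @return list of samples x embedDims coordinate matrices.
#' @export
embedEnsemble <- function(gem, config = embedConfig()) {
  X <- if (is(gem, "GEM")) exprValues(gem) else as.matrix(gem)
  n <- nrow(X)
  if (n < max(10, 3 * config@perplexity))
    stop(sprintf("need at least %d samples for perplexity %g",
                 ceiling(max(10, 3 * config@perplexity)), config@perplexity))
  if (config@logTransform) X <- log1p(X)
  P <- tsneAffinities(X, config@perplexity)
  lapply(seq_len(config@nEmbeddings), function(e)
    tsneLayout(P, dims = config@embedDims, seed = subSeed(config@seed, e),
               nIter = config@tsneIter))
}

#' HDBSCAN labels for every embedding of an ensemble
#'
#' @param embeddings list of coordinate matrices (from [embedEnsemble()]).
#' @param config an [EmbedConfig-class].
#' @return embeddings x samples integer label matrix; -1 marks noise.
#' @export
clusterEmbeddings <- function(embeddings, config = embedConfig()) {
  if (length(embeddings) == 0L) stop("no embeddings")
  n <- nrow(embeddings[[1L]])
  mcs <- if (is.na(config@minClusterSize)) max(5L, as.integer(round(n / 100)))
         else config@minClusterSize
  t(vapply(embeddings, function(Y) hdbscanLabels(Y, mcs), integer(n)))
}

#' Consensus partition of a clustering ensemble
#'
#' The co-association matrix records, for every sample pair, the fraction
#' of embeddings that place the pair in the same non-noise cluster
#' (embeddings where either member is noise are excluded from that pair's
#' denominator).  Average-linkage hierarchical clustering of
#' \code{1 - coAssociation} cut at \code{nClusters} gives the consensus
#' labels; with \code{nClusters = NA} the cut with the largest dendrogram
#' lifetime is used.
#'
#' @param labelMatrix embeddings x samples labels, -1 = noise.
#' @param nClusters consensus cluster count or NA.
#' @param sampleIds optional sample names for the labels.
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(labelMatrix, nClusters = NA, sampleIds = NULL) {
  if (nrow(labelMatrix) < 1L) stop("need at least one labeling")
  n <- ncol(labelMatrix)
  if (!is.na(nClusters) && nClusters > n)
    stop("nClusters exceeds the number of samples")
  num <- den <- matrix(0, n, n)
  for (e in seq_len(nrow(labelMatrix))) {
    l <- labelMatrix[e, ]
    ok <- l >= 0L
    bothOk <- outer(ok, ok, "&")
    same <- outer(l, l, "==") & bothOk
    num <- num + same
    den <- den + bothOk
  }
  A <- ifelse(den > 0, num / den, 0)
  diag(A) <- 1
  A <- (A + t(A)) / 2
  if (!is.null(sampleIds)) dimnames(A) <- list(sampleIds, sampleIds)

  if (n == 1L) {
    labels <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(1 - A), method = "average")
    k <- if (is.na(nClusters)) {
      h <- hc$height
      life <- c(diff(h), 1 - h[length(h)])   # last lifetime: up to max dissimilarity
      if (all(life <= 1e-12)) 1L else n - which.max(life)
    } else as.integer(nClusters)
    k <- max(1L, min(k, n))
    labels <- as.integer(stats::cutree(hc, k = k))
  }
  names(labels) <- sampleIds
  new("ConsensusResult", labelMatrix = labelMatrix,
      consensusLabels = labels, coAssociation = A)
}

#' @describeIn consensusCluster consensus labels accessor
#' @param result a [ConsensusResult-class]
#' @export
consensusLabels <- function(result) result@consensusLabels

#' @describeIn consensusCluster co-association matrix accessor
#' @export
coAssociation <- function(result) result@coAssociation

# Chi-squared statistic for a 2x2 table by the plain sum((O-E)^2/E) formula
# (no continuity correction).
chisq2x2 <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E == 0)) return(list(stat = NA_real_, p = NA_real_, expected = E))
  stat <- sum((O - E)^2 / E)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = E)
}

#' Attribute enrichment of consensus clusters
#'
#' For each (cluster, attribute level) pair a 2x2 contingency table
#' (in/out of cluster x has/lacks the level) is tested with a 1-df
#' chi-squared, \code{sum((O-E)^2/E)}, without continuity correction.  Age
#' is dichotomized at 40 years; missing values are excluded from the
#' denominators; a cluster is flagged enriched for a level when p < pCut
#' and the observed in-cluster count exceeds its expectation.
#'
#' @param result a [ConsensusResult-class] with named labels, or a named
#'   integer label vector.
#' @param meta metadata data.frame with \code{sample_id} and attribute
#'   columns.
#' @param pCut enrichment p-value cutoff (default 0.001).
#' @param attributes which metadata columns to test.
#' @return data.frame with columns cluster, attribute, level, countIn,
#'   countOut, statistic, p, enriched.
#' @export
attributeEnrichment <- function(result, meta, pCut = 0.001,
                                attributes = c("tumor_type", "sample_type",
                                               "gender", "race", "ethnicity",
                                               "stage", "age")) {
  labels <- if (is(result, "ConsensusResult")) consensusLabels(result) else result
  if (is.null(names(labels))) stop("labels must be named by sample id")
  idx <- match(names(labels), meta$sample_id)
  if (anyNA(idx)) stop("metadata does not cover all labeled samples")
  meta <- meta[idx, , drop = FALSE]
  rows <- list()
  for (cl in sort(unique(labels))) {
    inCl <- labels == cl
    if (sum(inCl) == 0L) stop(sprintf("empty cluster %s", cl))
    for (a in attributes) {
      vals <- meta[[a]]
      if (a == "age")
        vals <- ifelse(is.na(vals), NA_character_,
                       ifelse(vals >= 40, "age >= 40", "age < 40"))
      ok <- !is.na(vals) & vals != ""
      lv <- unique(vals[ok])
      if (length(lv) < 2L) {
        message(sprintf("attribute '%s' has fewer than two observed levels; skipped", a))
        next
      }
      for (level in sort(lv)) {
        has <- vals == level
        O <- matrix(c(sum(inCl & ok & has), sum(inCl & ok & !has),
                      sum(!inCl & ok & has), sum(!inCl & ok & !has)),
                    2, 2, byrow = TRUE)
        cs <- chisq2x2(O)
        if (is.na(cs$stat)) next
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, attribute = a, level = level,
          countIn = O[1L, 1L], countOut = O[2L, 1L],
          statistic = cs$stat, p = cs$p,
          enriched = cs$p < pCut && O[1L, 1L] > cs$expected[1L, 1L])
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(cluster = integer(0), attribute = character(0),
                      level = character(0), countIn = integer(0),
                      countOut = integer(0), statistic = numeric(0),
                      p = numeric(0), enriched = logical(0)))
  do.call(rbind, rows)
}

#' Full embedding / clustering / consensus / enrichment pipeline
#'
#' @param gem a [GEM-class].
#' @param meta sample metadata (NULL to skip enrichment).
#' @param config an [EmbedConfig-class].
#' @param pCut enrichment cutoff.
#' @param attributes metadata columns to test.
#' @return list with \code{consensus} (a [ConsensusResult-class]) and
#'   \code{enrichment} (data.frame or NULL).
#' @export
consensusPipeline <- function(gem, meta = NULL, config = embedConfig(),
                              pCut = 0.001,
                              attributes = c("tumor_type", "sample_type",
                                             "gender", "race", "ethnicity",
                                             "stage", "age")) {
  emb <- embedEnsemble(gem, config)
  lm <- clusterEmbeddings(emb, config)
  nCl <- if (is.na(config@nConsensusClusters)) NA else config@nConsensusClusters
  cons <- consensusCluster(lm, nCl, sampleIds = sampleIds(gem))
  enr <- if (!is.null(meta))
    attributeEnrichment(cons, meta, pCut, attributes) else NULL
  list(consensus = cons, enrichment = enr)
}

#' Size/replicate protocol of the background-classification experiment
#'
#' Twenty replicates at subset sizes 25-200 (step 25), ten at 225, 250,
#' 300, 400 and 500, and five at 1000.
#'
#' @return data.frame with columns \code{size} and \code{reps}.
#' @export
backgroundProtocol <- function() {
  data.frame(size = c(seq(25, 200, by = 25), 225, 250, 300, 400, 500, 1000),
             reps = c(rep(20L, 8L), rep(10L, 5L), 5L))
}

#' Background classification potential of random transcript subsets
#'
#' Draws random transcript subsets of the given sizes, runs the full
#' embedding/clustering/consensus pipeline on each, and records the
#' fraction of consensus clusters enriched for at least one tumor type.
#' Sufficiently large random subsets classify samples almost as well as
#' curated markers -- the background classification potential.
#'
#' @param gem a [GEM-class].
#' @param meta sample metadata.
#' @param protocol data.frame with columns \code{size} and \code{reps}
#'   (default [backgroundProtocol()]).
#' @param config an [EmbedConfig-class]; use a reduced \code{nEmbeddings}
#'   for tractable run times.
#' @param pCut enrichment cutoff.
#' @param seed master seed; each (size, replicate) cell derives its own
#'   sub-seed.
#' @return data.frame with columns size, replicate, nClusters,
#'   fractionEnriched.
#' @export
backgroundExperiment <- function(gem, meta, protocol = backgroundProtocol(),
                                 config = embedConfig(nEmbeddings = 20),
                                 pCut = 0.001, seed = 1L) {
  txs <- transcriptIds(gem)
  if (any(protocol$size > length(txs)))
    stop("subset size exceeds the number of transcripts")
  out <- list()
  for (i in seq_len(nrow(protocol))) {
    sz <- protocol$size[i]
    for (r in seq_len(protocol$reps[i])) {
      cellSeed <- subSeed(seed, sz * 137L + r)
      pick <- withSeed(cellSeed, sample(txs, sz))
      cfg <- config
      cfg@seed <- cellSeed
      res <- consensusPipeline(gem[, match(pick, txs)], meta, cfg,
                               pCut = pCut, attributes = "tumor_type")
      enr <- res$enrichment
      labs <- consensusLabels(res$consensus)
      k <- length(unique(labs))
      frac <- if (is.null(enr) || nrow(enr) == 0L) 0 else {
        enrCl <- unique(enr$cluster[enr$enriched])
        length(enrCl) / k
      }
      out[[length(out) + 1L]] <- data.frame(size = sz, replicate = r,
                                            nClusters = k,
                                            fractionEnriched = frac)
    }
  }
  do.call(rbind, out)
}
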