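threeClassGem <- function(seed = 71, perClass = 20) {
  generateGem(synthConfig(nClasses = 3, samplesPerClass = perClass,
                          nBackgroundDiff = 100, nNoise = 60, seed = seed))
}

test_that("embedding ensembles are deterministic and validate perplexity", {
  sim <- threeClassGem()
  cfg <- embedConfig(nEmbeddings = 2, perplexity = 10, tsneIter = 60, seed = 4)
  e1 <- embedEnsemble(sim$gem, cfg)
  e2 <- embedEnsemble(sim$gem, cfg)
  expect_identical(e1, e2)
  expect_false(identical(e1[[1]], e1[[2]]))   # different random inits
  tiny <- sim$gem[1:5, ]
  expect_error(embedEnsemble(tiny, embedConfig(perplexity = 30)), "samples")
})

test_that("well-separated classes stay separated in most embeddings", {
  sim <- threeClassGem(72)
  cl <- sim$truth$classLabels
  emb <- embedEnsemble(sim$gem, embedConfig(nEmbeddings = 10, perplexity = 10,
                                            seed = 5))
  sil <- vapply(emb, function(Y) silhouetteOracle(Y, cl), numeric(1L))
  expect_gte(mean(sil > 0.5), 0.9)
})

test_that("hdbscan finds blobs, flags no structure in one blob, and is stable", {
  one <- withr::with_seed(1, matrix(rnorm(100), 50, 2))
  expect_equal(unique(hdbscanLabels(one, 5)), 1L)
  two <- withr::with_seed(2, rbind(matrix(rnorm(60, 0, 0.5), 30, 2),
                                   matrix(rnorm(60, 20, 0.5), 30, 2)))
  lab <- hdbscanLabels(two, 5)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(unique(lab[1:30])), 1L)
  expect_equal(length(unique(lab[31:60])), 1L)
  expect_false(lab[1] == lab[31])
  # permutation invariance up to label matching
  perm <- withr::with_seed(3, sample(60))
  labP <- hdbscanLabels(two[perm, ], 5)
  skipIfNot("mclust")
  expect_equal(mclust::adjustedRandIndex(labP, lab[perm]), 1)
})

test_that("consensus of agreeing partitions is that partition", {
  truth <- rep(1:3, each = 4)
  relabelings <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  lm <- t(vapply(relabelings, function(p) p[truth], integer(12)))
  res <- consensusCluster(lm, sampleIds = sprintf("S%02d", 1:12))
  skipIfNot("mclust")
  expect_equal(mclust::adjustedRandIndex(consensusLabels(res), truth), 1)
  A <- coAssociation(res)
  expect_true(all(A %in% c(0, 1)))
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(1, 12), ignore_attr = TRUE)
})

test_that("consensus survives a minority of random labelings", {
  truth <- rep(1:3, each = 4)
  lm <- matrix(0L, 10, 12)
  for (e in 1:8) lm[e, ] <- truth
  lm[9, ] <- withr::with_seed(5, sample(1:3, 12, TRUE))
  lm[10, ] <- withr::with_seed(6, sample(1:2, 12, TRUE))
  res <- consensusCluster(lm, nClusters = 3)
  skipIfNot("mclust")
  expect_equal(mclust::adjustedRandIndex(consensusLabels(res), truth), 1)
  expect_error(consensusCluster(lm, nClusters = 13), "exceeds")
})

test_that("noise labels are excluded pair-wise from co-association", {
  lm <- rbind(c(1L, 1L, -1L), c(1L, 2L, 1L))
  A <- coAssociation(consensusCluster(lm, nClusters = 1))
  expect_equal(A[1, 2], 1 / 2)   # agree in embedding 1, disagree in 2
  expect_equal(A[1, 3], 1)       # only embedding 2 counts for this pair
  expect_equal(A[2, 3], 0)
})

test_that("cluster attribute enrichment matches the contingency formula", {
  labels <- setNames(c(rep(1L, 50), rep(2L, 450)), sprintf("S%03d", 1:500))
  meta <- data.frame(sample_id = names(labels),
                     tumor_type = c(rep("A", 45), rep("B", 5),
                                    rep("A", 55), rep("B", 395)))
  enr <- attributeEnrichment(labels, meta, attributes = "tumor_type")
  rowA1 <- enr[enr$cluster == 1 & enr$level == "A", ]
  # oracle value computed from sum((O-E)^2/E) on [[45,5],[55,395]]
  expect_equal(rowA1$statistic, 6125 / 36, tolerance = 1e-10)
  expect_equal(rowA1$statistic,
               chisqOracle(matrix(c(45, 5, 55, 395), 2, byrow = TRUE)))
  expect_equal(rowA1$p, pchisq(6125 / 36, 1, lower.tail = FALSE))
  expect_true(rowA1$enriched)
})

test_that("clusters mirroring the global composition are never enriched", {
  labels <- setNames(rep(1:2, each = 40), sprintf("S%03d", 1:80))
  meta <- data.frame(sample_id = names(labels),
                     tumor_type = rep(rep(c("A", "B"), each = 20), 2))
  enr <- attributeEnrichment(labels, meta, attributes = "tumor_type")
  expect_false(any(enr$enriched))
  expect_true(all(abs(enr$statistic) < 1e-12))
})

test_that("age is dichotomized at 40 and missing levels are excluded", {
  labels <- setNames(rep(1:2, each = 30), sprintf("S%03d", 1:60))
  meta <- data.frame(sample_id = names(labels),
                     age = c(rep(25, 28), NA, NA, rep(60, 30)))
  enr <- attributeEnrichment(labels, meta, attributes = "age")
  young <- enr[enr$cluster == 1 & enr$level == "age < 40", ]
  expect_equal(young$countIn + young$countOut, 28)   # NAs dropped
  expect_true(young$enriched)
})

test_that("every emitted chi-squared equals the explicit formula", {
  sim <- threeClassGem(73)
  cl <- sim$truth$classLabels
  labels <- setNames(as.integer(cl), names(cl))
  enr <- attributeEnrichment(labels, sim$metadata)
  sizes <- table(labels)
  for (i in seq_len(nrow(enr))) {
    r <- enr[i, ]
    nIn <- sizes[[as.character(r$cluster)]]
    vals <- sim$metadata[[r$attribute]]
    if (r$attribute == "age") vals <- ifelse(vals >= 40, "age >= 40", "age < 40")
    ok <- !is.na(vals) & vals != ""
    nInOk <- sum(ok[labels == r$cluster])
    nOutOk <- sum(ok[labels != r$cluster])
    O <- matrix(c(r$countIn, nInOk - r$countIn,
                  r$countOut, nOutOk - r$countOut), 2, byrow = TRUE)
    expect_equal(r$statistic, chisqOracle(O), tolerance = 1e-10)
  }
})

test_that("the full pipeline recovers planted classes and attributes", {
  sim <- threeClassGem(74, perClass = 25)
  cfg <- embedConfig(nEmbeddings = 12, perplexity = 15, seed = 7)
  res <- consensusPipeline(quantileNormalize(sim$gem), sim$metadata, cfg)
  labs <- consensusLabels(res$consensus)
  skipIfNot("mclust")
  expect_gte(mclust::adjustedRandIndex(labs, sim$truth$classLabels), 0.9)
  enr <- res$enrichment
  for (tt in unique(sim$metadata$tumor_type))
    expect_true(any(enr$enriched & enr$attribute == "tumor_type" &
                      enr$level == tt))
})

test_that("the background protocol table matches the published design", {
  p <- backgroundProtocol()
  expect_equal(p$size, c(25, 50, 75, 100, 125, 150, 175, 200,
                         225, 250, 300, 400, 500, 1000))
  expect_equal(p$reps, c(rep(20L, 8), rep(10L, 5), 5L))
  expect_equal(sum(p$reps), 215L)
})

test_that("a full-size background draw reproduces the full-GEM pipeline", {
  sim <- threeClassGem(75)
  gem <- quantileNormalize(sim$gem)
  cfg <- embedConfig(nEmbeddings = 8, perplexity = 12)
  bg <- backgroundExperiment(gem, sim$metadata,
                             protocol = data.frame(size = nTranscripts(gem),
                                                   reps = 1L),
                             config = cfg, seed = 3)
  expect_equal(nrow(bg), 1L)
  cellSeed <- dqcsort:::subSeed(3, nTranscripts(gem) * 137L + 1L)
  cfg@seed <- cellSeed
  ref <- consensusPipeline(gem, sim$metadata, cfg, attributes = "tumor_type")
  k <- length(unique(consensusLabels(ref$consensus)))
  frac <- length(unique(ref$enrichment$cluster[ref$enrichment$enriched])) / k
  expect_equal(bg$nClusters, k)
  expect_equal(bg$fractionEnriched, frac)
})
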