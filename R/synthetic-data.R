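#' Configuration for the synthetic GEM generator
#'
#' Describes a multi-class expression study with three planted transcript
#' strata: a small set of strong class-specific "core" markers, a large
#' diffuse layer of weakly class-differential transcripts (the substrate of
#' the background classification potential), and pure-noise transcripts.
#' Expression follows a log-normal model: \code{value = exp(N(baseLogMean +
#' shift, logSd))}, so values are non-negative and continuous like
#' RSEM-style abundances.  Shifts are in natural-log units.
#'
#' @slot nClasses number of sample classes.
#' @slot samplesPerClass integer vector (recycled to \code{nClasses}).
#' @slot nCoreMarkersPerClass strong markers planted per class.
#' @slot coreEffect log-scale mean shift of a core marker in its own class.
#' @slot nBackgroundDiff number of weakly differential transcripts.
#' @slot backgroundEffect per-class shifts of background-differential
#'   transcripts are drawn uniformly from \code{[-backgroundEffect,
#'   backgroundEffect]}; must be well below \code{coreEffect}.
#' @slot nNoise number of class-independent transcripts.
#' @slot baseLogMean,logSd log-scale location and spread of expression.
#' @slot attrAssoc named list of per-class category probability matrices
#'   (rows = classes, columns = named attribute levels, rows sum to 1);
#'   attributes listed here are the planted metadata associations.
#' @slot ageClassMeans per-class mean age in years (recycled); ages are
#'   normal with sd \code{ageSd}.
#' @slot ageSd age standard deviation in years.
#' @slot seed integer seed; one global seed drives fixed-offset sub-streams
#'   for expression, attributes and ages.
#' @export
setClass("SynthConfig",
         representation(nClasses = "integer", samplesPerClass = "integer",
                        nCoreMarkersPerClass = "integer", coreEffect = "numeric",
                        nBackgroundDiff = "integer", backgroundEffect = "numeric",
                        nNoise = "integer", baseLogMean = "numeric",
                        logSd = "numeric", attrAssoc = "list",
                        ageClassMeans = "numeric", ageSd = "numeric",
                        seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@nClasses < 1L) return("need at least one class")
  if (any(object@samplesPerClass < 0L)) return("negative samples per class")
  if (object@nCoreMarkersPerClass < 0L || object@nBackgroundDiff < 0L ||
      object@nNoise < 0L) return("transcript counts must be >= 0")
  if (object@backgroundEffect < 0) return("backgroundEffect must be >= 0")
  if (object@coreEffect <= object@backgroundEffect)
    return("coreEffect must exceed backgroundEffect")
  if (object@logSd < 0) return("logSd must be >= 0")
  for (a in names(object@attrAssoc)) {
    p <- object@attrAssoc[[a]]
    if (!is.matrix(p) || nrow(p) != object@nClasses || is.null(colnames(p)))
      return(sprintf("attrAssoc[['%s']] must be an nClasses x levels matrix with level names", a))
    if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-8))
      return(sprintf("attrAssoc[['%s']] rows must be probabilities summing to 1", a))
  }
  TRUE
})

#' Create a synthetic study configuration
#'
#' Defaults describe the package's reference study: 3 classes of 50 samples,
#' 10 core markers per class with a 4 log-unit effect against logSd 0.5, 600
#' weakly differential transcripts (effect bounded by 1 log-unit), and 370
#' pure-noise transcripts, for 1000 transcripts in total; gender and stage
#' are planted as class-associated attributes and age is class-shifted
#' around the 40-year dichotomy.
#'
#' @param nClasses,samplesPerClass,nCoreMarkersPerClass,coreEffect see slots
#' @param nBackgroundDiff,backgroundEffect,nNoise,baseLogMean,logSd see slots
#' @param attrAssoc,ageClassMeans,ageSd,seed see slots
#' @return A validated [SynthConfig-class].
#' @examples
#' cfg <- synthConfig(seed = 7)
#' sim <- generateGem(cfg)
#' sim$gem
#' @export
synthConfig <- function(nClasses = 3, samplesPerClass = 50,
                        nCoreMarkersPerClass = 10, coreEffect = 4,
                        nBackgroundDiff = 600, backgroundEffect = 1,
                        nNoise = 370, baseLogMean = 6, logSd = 0.5,
                        attrAssoc = defaultAttrAssoc(nClasses),
                        ageClassMeans = c(35, 55, 60), ageSd = 8,
                        seed = 1L) {
  new("SynthConfig",
      nClasses = as.integer(nClasses),
      samplesPerClass = as.integer(rep_len(samplesPerClass, nClasses)),
      nCoreMarkersPerClass = as.integer(nCoreMarkersPerClass),
      coreEffect = as.numeric(coreEffect),
      nBackgroundDiff = as.integer(nBackgroundDiff),
      backgroundEffect = as.numeric(backgroundEffect),
      nNoise = as.integer(nNoise),
      baseLogMean = as.numeric(baseLogMean), logSd = as.numeric(logSd),
      attrAssoc = attrAssoc,
      ageClassMeans = rep_len(as.numeric(ageClassMeans), nClasses),
      ageSd = as.numeric(ageSd), seed = as.integer(seed))
}

#' Default planted attribute associations
#'
#' Gender and tumor stage skewed by class, strongly enough that a
#' chi-squared test of attribute against class rejects at p < 0.001 for
#' realistic per-class sample sizes.
#'
#' @param nClasses number of classes.
#' @return named list of probability matrices suitable for
#'   \code{\link{synthConfig}}.
#' @export
defaultAttrAssoc <- function(nClasses = 3) {
  gender <- matrix(0.5, nClasses, 2, dimnames = list(NULL, c("male", "female")))
  for (k in seq_len(nClasses))
    gender[k, ] <- if (k %% 2L == 1L) c(0.15, 0.85) else c(0.85, 0.15)
  stages <- c("stage i", "stage ii", "stage iii", "stage iv")
  stage <- matrix(0.05, nClasses, 4, dimnames = list(NULL, stages))
  for (k in seq_len(nClasses)) {
    heavy <- ((k - 1L) %% 4L) + 1L
    stage[k, ] <- 0.15 / 3
    stage[k, heavy] <- 0.85
  }
  list(gender = gender, stage = stage)
}

#' Generate a synthetic GEM with metadata and ground truth
#'
#' @param config a [SynthConfig-class].
#' @return list with components \code{gem} ([GEM-class], samples x
#'   transcripts), \code{metadata} (data.frame with the package's standard
#'   columns), and \code{truth}: a list holding \code{classLabels} (named
#'   integer), \code{coreMarkerIds} (list per class), \code{backgroundDiffIds},
#'   \code{noiseIds}, and \code{plantedAttributes}.
#' @details Identical seeds give byte-identical output.  Core markers of
#'   class k are shifted by \code{coreEffect} in class-k samples only;
#'   background-differential transcripts get independent per-class uniform
#'   shifts in \code{[-backgroundEffect, backgroundEffect]}; noise
#'   transcripts ignore class.
#' @export
generateGem <- function(config) {
  validObject(config)
  K <- config@nClasses
  nPer <- config@samplesPerClass
  n <- sum(nPer)
  nCore <- K * config@nCoreMarkersPerClass
  Tn <- nCore + config@nBackgroundDiff + config@nNoise
  if (n == 0L || Tn == 0L) stop("invalid config: zero samples or zero transcripts")

  cls <- rep(seq_len(K), times = nPer)
  sampleId <- sprintf("S%04d", seq_len(n))
  txId <- sprintf("TX%05d", seq_len(Tn))
  coreIdx <- if (nCore > 0L)
    split(seq_len(nCore), rep(seq_len(K), each = config@nCoreMarkersPerClass))
  else rep(list(integer()), K)
  bgIdx <- seq_len(config@nBackgroundDiff) + nCore
  noiseIdx <- seq_len(config@nNoise) + nCore + config@nBackgroundDiff

  logM <- withSeed(subSeed(config@seed, 101L), {
    shift <- matrix(0, K, Tn)                      # per-class log-mean shifts
    for (k in seq_len(K)) shift[k, coreIdx[[k]]] <- config@coreEffect
    if (length(bgIdx) > 0L)
      shift[, bgIdx] <- matrix(stats::runif(K * length(bgIdx),
                                            -config@backgroundEffect,
                                            config@backgroundEffect),
                               K, length(bgIdx))
    mu <- config@baseLogMean + shift[cls, , drop = FALSE]
    mu + matrix(stats::rnorm(n * Tn, 0, config@logSd), n, Tn)
  })
  values <- exp(logM)
  dimnames(values) <- list(sampleId, txId)

  meta <- data.frame(sample_id = sampleId,
                     tumor_type = sprintf("TT%02d", cls),
                     sample_type = "Primary Tumor",
                     age = NA_real_, gender = NA_character_,
                     race = NA_character_, ethnicity = NA_character_,
                     stage = NA_character_, stringsAsFactors = FALSE)
  meta$age <- withSeed(subSeed(config@seed, 303L),
                       stats::rnorm(n, config@ageClassMeans[cls], config@ageSd))
  withSeed(subSeed(config@seed, 202L), {
    for (a in c("gender", "race", "ethnicity", "stage")) {
      if (a %in% names(config@attrAssoc)) {
        p <- config@attrAssoc[[a]]
        meta[[a]] <- vapply(cls, function(k)
          sample(colnames(p), 1L, prob = p[k, ]), character(1L))
      } else {
        lv <- switch(a,
                     gender = c("male", "female"),
                     race = c("white", "black or african american", "asian"),
                     ethnicity = c("not hispanic or latino", "hispanic or latino"),
                     stage = c("stage i", "stage ii", "stage iii", "stage iv"))
        meta[[a]] <- sample(lv, n, replace = TRUE)
      }
    }
  })

  truth <- list(classLabels = stats::setNames(cls, sampleId),
                coreMarkerIds = lapply(coreIdx, function(i) txId[i]),
                backgroundDiffIds = txId[bgIdx],
                noiseIds = txId[noiseIdx],
                plantedAttributes = names(config@attrAssoc))
  list(gem = GEM(values), metadata = meta, truth = truth)
}

#' Mark a random sample subset as "Solid Tissue Normal"
#'
#' Emulates the label contamination found in real tumor cohorts, where a
#' small fraction of samples carry the cohort's tumor-type label but are in
#' fact normal tissue.  Expression values and tumor-type labels are left
#' untouched; only \code{sample_type} changes.
#'
#' @param gem a [GEM-class] (defines the eligible sample set).
#' @param meta sample metadata data.frame with a \code{sample_id} column.
#' @param fraction fraction of samples to mark, in \code{[0, 1]}; the count
#'   is \code{floor(fraction * n + 0.5)}.
#' @param seed integer seed for the random subset.
#' @return the metadata with \code{sample_type} updated.
#' @export
injectNormals <- function(gem, meta, fraction, seed = 1L) {
  assertScalar(fraction, "fraction", 0, 1)
  ids <- sampleIds(gem)
  nMark <- floor(fraction * length(ids) + 0.5)
  marked <- withSeed(seed, sample(ids, nMark))
  meta$sample_type[meta$sample_id %in% marked] <- "Solid Tissue Normal"
  meta
}
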