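#' Gap cut of one SVD eigenvector
#'
#' Sorts the absolute component values in decreasing order and looks for a
#' close group of large values followed by a gap.  The cut position p
#' (restricted to the first half of the vector, which prevents degenerate
#' near-tail gaps on noise-dominated dimensions) maximizes the ratio
#' \code{a_p / a_(p+1)}; if that ratio reaches \code{minGapRatio} the first
#' p components are selected, otherwise nothing is.  Ties in the maximal
#' ratio resolve to the smallest p.
#'
#' @param v numeric vector of eigenvector components (one Vt row).
#' @param minGapRatio minimal ratio across the gap, default 3.
#' @return integer indices of the selected components (possibly empty),
#'   with the gap ratio and the magnitude threshold attached as attributes
#'   \code{"gapRatio"} and \code{"threshold"}.
#' @examples
#' componentCut(c(0.9, 0.85, 0.8, 0.01, 0.009))  # selects the first three
#' @export
componentCut <- function(v, minGapRatio = 3) {
  if (length(v) < 2L) stop("vector too short for a gap cut")
  a <- abs(v)
  if (all(a == 0)) stop("all-zero eigenvector")
  o <- order(a, decreasing = TRUE)
  s <- a[o]
  pmax_ <- ceiling(length(v) / 2)
  if (pmax_ < 1L) return(integer(0))
  ratio <- s[seq_len(pmax_)] / s[seq_len(pmax_) + 1L]
  ratio[!is.finite(ratio)] <- Inf                  # a_{p+1} = 0: infinite gap
  p <- which.max(ratio)                            # smallest p on ties
  out <- if (ratio[p] >= minGapRatio) o[seq_len(p)] else integer(0)
  attr(out, "gapRatio") <- unname(ratio[p])
  attr(out, "threshold") <- if (length(out) > 0L) s[p] else NA_real_
  out
}

#' Select important transcripts from SVD eigenvectors
#'
#' Applies [componentCut()] to the requested rows of Vt (the directions
#' where the DQC-evolved data separates) and returns the union of the
#' selected transcripts, with per-dimension bookkeeping.
#'
#' @param f an [SVDFactors-class] of a [GEM-class] (so Vt columns carry
#'   transcript ids).
#' @param dims SVD dimensions (Vt row indices) to examine; must be
#'   non-empty.
#' @param minGapRatio passed to [componentCut()].
#' @param transcriptIds optional ids for the Vt columns; defaults to
#'   \code{colnames}.
#' @return character vector of selected transcript ids (in order of first
#'   selection), with a per-dimension data.frame (\code{dimension},
#'   \code{threshold}, \code{count}) attached as attribute
#'   \code{"perDimension"}.
#' @export
selectFeatures <- function(f, dims, minGapRatio = 3, transcriptIds = NULL) {
  if (length(dims) == 0L) stop("dims must be non-empty")
  if (any(dims < 1L) || any(dims > nrow(f@Vt)))
    stop("dims outside the available Vt rows")
  ids <- transcriptIds
  if (is.null(ids)) ids <- colnames(f@Vt)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(f@Vt)))
  sel <- character(0)
  per <- data.frame(dimension = integer(0), threshold = numeric(0),
                    count = integer(0))
  for (d in dims) {
    idx <- componentCut(f@Vt[d, ], minGapRatio)
    per <- rbind(per, data.frame(dimension = as.integer(d),
                                 threshold = attr(idx, "threshold"),
                                 count = length(idx)))
    sel <- union(sel, ids[idx])
  }
  attr(sel, "perDimension") <- per
  sel
}

#' Iterative select-remove-repeat feature layers
#'
#' Repeatedly: decompose the current GEM by SVD, (optionally) DQC-evolve
#' the reduced coordinates to find the separating dimensions, gap-cut those
#' eigenvectors, record the selected transcripts as a layer, remove them,
#' and continue on the remainder.  Early layers hold the strong class
#' markers; later layers probe the diffuse background classification
#' signal.
#'
#' @param gem a [GEM-class] (normalize first if desired).
#' @param nIterations number of layers to attempt.
#' @param dimsPerIteration number of leading SVD dimensions examined per
#'   iteration (default 12).
#' @param minGapRatio passed to [componentCut()].
#' @param useDqc if TRUE, DQC-evolve the reduced coordinates each iteration
#'   and keep only dimensions passing [separatingDimensions()]; if FALSE
#'   (the expedited mode, default) the first \code{dimsPerIteration}
#'   dimensions are used directly.
#' @param dqcCfg a [DQCConfig-class] for the evolution (useDqc mode).
#' @param minScore separation score cutoff (useDqc mode).
#' @param checker optional callback \code{function(layer, gemSelected,
#'   gemRemaining)} invoked after each iteration, e.g. to verify that the
#'   selected set alone still separates the samples; its results are
#'   collected and returned as attribute \code{"checks"}.
#' @return list of [FeatureLayer-class] objects, with attributes
#'   \code{"status"} (\code{"ok"} or \code{"stopped_early"}) and
#'   \code{"checks"}.
#' @export
iterateLayers <- function(gem, nIterations, dimsPerIteration = 12,
                          minGapRatio = 3, useDqc = FALSE,
                          dqcCfg = dqcConfig(), minScore = 0.5,
                          checker = NULL) {
  if (nIterations < 1L) stop("nIterations must be >= 1")
  cur <- gem
  layers <- list()
  checks <- list()
  status <- "ok"
  emptyRun <- 0L
  for (it in seq_len(nIterations)) {
    f <- svdDecompose(cur)
    nd <- min(dimsPerIteration, length(singularValues(f)))
    dims <- seq_len(nd)
    if (useDqc) {
      traj <- dqcEvolve(reducedCoordinates(f, nd), dqcCfg)
      sep <- separatingDimensions(traj, nFrames(traj), minScore)
      if (length(sep) > 0L) dims <- as.integer(sep)
    }
    sel <- selectFeatures(f, dims, minGapRatio)
    layer <- new("FeatureLayer", iteration = as.integer(it),
                 transcripts = as.character(sel),
                 perDimension = attr(sel, "perDimension"),
                 remaining = as.integer(nTranscripts(cur) - length(sel)))
    layers[[it]] <- layer
    if (length(sel) == 0L) {
      emptyRun <- emptyRun + 1L
      if (emptyRun >= 2L) {
        warning(sprintf("empty selection at iterations %d-%d; stopping early",
                        it - 1L, it))
        status <- "stopped_early"
        break
      }
    } else {
      emptyRun <- 0L
      if (!is.null(checker)) {
        keepCols <- match(sel, transcriptIds(cur))
        checks[[it]] <- checker(layer,
                                cur[, keepCols],
                                cur[, -keepCols])
      }
      if (length(sel) >= nTranscripts(cur)) break  # nothing left to iterate on
      cur <- cur[, -match(sel, transcriptIds(cur))]
    }
    if (nTranscripts(cur) < 2L) break
  }
  attr(layers, "status") <- status
  attr(layers, "checks") <- checks
  layers
}

#' Write feature layers to TSV + JSON summary
#'
#' @param layers output of [iterateLayers()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeLayers <- function(layers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(layers, function(l)
    if (length(l@transcripts) > 0L)
      data.frame(iteration = l@iteration, transcript_id = l@transcripts)
    else NULL))
  utils::write.table(rows, file.path(dir, "layers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- lapply(layers, function(l)
    list(iteration = l@iteration, size = length(l@transcripts),
         remaining = l@remaining,
         thresholds = l@perDimension$threshold))
  jsonlite::write_json(summ, file.path(dir, "layers.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
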