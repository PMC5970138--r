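#' Read a GMT annotation file
#'
#' Standard GMT: one term per line, tab-separated as \code{term_id,
#' description, member, member, ...}.  Duplicate members within a term are
#' collapsed.  The background defaults to the union of all members; pass an
#' explicit universe to override (e.g. the GEM transcript set).
#'
#' @param path GMT file path.
#' @param background optional explicit background transcript set; members
#'   outside it are dropped.
#' @return an [AnnotationMap-class].
#' @export
readGmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file")
  terms <- list()
  termNames <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need term, description and at least one member",
                   i, length(f)))
    id <- f[1L]
    if (id %in% names(terms)) stop(sprintf("duplicate term id '%s' (line %d)", id, i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!is.null(background)) members <- intersect(members, background)
    if (length(members) == 0L) next
    terms[[id]] <- members
    termNames[id] <- f[2L]
  }
  if (length(terms) == 0L) stop("no usable terms in GMT file")
  bg <- if (is.null(background)) sort(unique(unlist(terms, use.names = FALSE)))
        else sort(unique(background))
  new("AnnotationMap", terms = terms, termNames = termNames, background = bg)
}

#' Term over-representation of a transcript list
#'
#' One-sided hypergeometric tail test per term: with background size N,
#' term size K, list size n and overlap k, \code{p = P(X >= k)} for
#' \code{X ~ Hypergeom(N, K, n)}, followed by Benjamini-Hochberg correction
#' across the tested terms.  A term is enriched when q < fdrCut.
#'
#' @param transcripts character vector of transcript ids; ids outside the
#'   background are dropped with a notice.
#' @param ann an [AnnotationMap-class].
#' @param fdrCut FDR threshold (default 0.01).
#' @return data.frame with columns term, name, k, n, K, N, p, q, enriched,
#'   sorted by p.
#' @export
termEnrich <- function(transcripts, ann, fdrCut = 0.01) {
  transcripts <- unique(transcripts)
  inBg <- transcripts %in% ann@background
  if (any(!inBg))
    message(sprintf("%d transcript(s) outside the background dropped",
                    sum(!inBg)))
  lst <- transcripts[inBg]
  if (length(lst) == 0L) stop("no transcripts left after background intersection")
  N <- length(ann@background)
  n <- length(lst)
  rows <- lapply(names(ann@terms), function(tm) {
    members <- ann@terms[[tm]]
    K <- length(members)
    k <- length(intersect(members, lst))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, name = unname(ann@termNames[tm]),
               k = k, n = n, K = K, N = N, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q < fdrCut
  out[order(out$p), , drop = FALSE]
}

#' Layer-by-term enrichment matrix
#'
#' Runs [termEnrich()] on every feature-selection layer and assembles the
#' terms x iterations matrix of enrichment flags, the per-term count of
#' flagged iterations (the repeat pattern of shared function across
#' layers), and per-layer enriched-term counts both raw and corrected for
#' layer size.
#'
#' @param layers list of [FeatureLayer-class] (from [iterateLayers()]).
#' @param ann an [AnnotationMap-class].
#' @param fdrCut FDR threshold per layer.
#' @return list with \code{flags} (logical terms x iterations matrix),
#'   \code{sharedCount} (named integer), and \code{layerSummary}
#'   (data.frame: iteration, layerSize, enrichedTerms,
#'   enrichedPerTranscript).
#' @export
layerTermMatrix <- function(layers, ann, fdrCut = 0.01) {
  if (length(layers) == 0L) stop("need at least one layer")
  termIds <- names(ann@terms)
  flags <- matrix(FALSE, length(termIds), length(layers),
                  dimnames = list(termIds,
                                  sprintf("%02d", vapply(layers, slot,
                                                         integer(1L), "iteration"))))
  summ <- data.frame(iteration = integer(0), layerSize = integer(0),
                     enrichedTerms = integer(0),
                     enrichedPerTranscript = numeric(0))
  for (j in seq_along(layers)) {
    l <- layers[[j]]
    sz <- length(l@transcripts)
    if (sz > 0L && any(l@transcripts %in% ann@background)) {
      e <- suppressMessages(termEnrich(l@transcripts, ann, fdrCut))
      flags[e$term[e$enriched], j] <- TRUE
    }
    nEnr <- sum(flags[, j])
    summ <- rbind(summ, data.frame(iteration = l@iteration, layerSize = sz,
                                   enrichedTerms = nEnr,
                                   enrichedPerTranscript =
                                     if (sz > 0L) nEnr / sz else 0))
  }
  list(flags = flags, sharedCount = rowSums(flags),
       layerSummary = summ)
}
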