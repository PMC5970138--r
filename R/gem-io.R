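#' Read a gene expression matrix from TSV
#'
#' File orientation is transcripts x samples (a header row of sample ids, a
#' first column of transcript ids), the common layout for RSEM-style
#' matrices.  The returned [GEM-class] is transposed into the package's
#' canonical samples x transcripts orientation; input ordering is preserved.
#'
#' @param path path to a tab-separated file.
#' @return A [GEM-class].
#' @export
readGem <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("GEM file needs a header and at least one transcript row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sampleId <- header[-1L]
  if (anyDuplicated(sampleId))
    stop("duplicate sample id(s): ",
         paste(unique(sampleId[duplicated(sampleId)]), collapse = ", "))
  ncols <- length(header)
  body <- fields[-1L]
  txId <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(txId))
    stop("duplicate transcript id(s): ",
         paste(unique(txId[duplicated(txId)]), collapse = ", "))
  vals <- matrix(NA_real_, length(body), length(sampleId))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncols)
      stop(sprintf("ragged row for transcript '%s' (%d fields, expected %d)",
                   row[1L], length(row), ncols))
    x <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1L]
      stop(sprintf("non-numeric value for transcript '%s', sample '%s'",
                   row[1L], sampleId[bad]))
    }
    if (any(x < 0))
      stop(sprintf("negative value for transcript '%s', sample '%s'",
                   row[1L], sampleId[which(x < 0)[1L]]))
    vals[i, ] <- x
  }
  dimnames(vals) <- list(txId, sampleId)
  GEM(t(vals))
}

#' Write a GEM as transcripts x samples TSV
#'
#' Inverse of [readGem()]: numeric content round-trips exactly (values are
#' written with 17 significant digits).
#'
#' @param gem a [GEM-class].
#' @param path output file path.
#' @export
writeGem <- function(gem, path) {
  v <- t(exprValues(gem))                          # transcripts x samples on disk
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("transcript_id", colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1L, function(x)
    paste(formatC(x, digits = 17, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  invisible(path)
}

metadataColumns <- c("sample_id", "tumor_type", "sample_type", "age",
                     "gender", "race", "ethnicity", "stage")

#' Read / write sample metadata
#'
#' Fixed-header TSV with columns \code{sample_id, tumor_type, sample_type,
#' age, gender, race, ethnicity, stage}.  Empty fields become NA, the
#' package's explicit missing category (excluded from enrichment
#' denominators).
#'
#' @param path file path.
#' @return data.frame with the standard columns.
#' @export
readSampleMetadata <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing <- setdiff(metadataColumns, names(m))
  if (length(missing) > 0L)
    stop("metadata file lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("duplicate sample ids in metadata")
  m$age <- as.numeric(m$age)
  m[metadataColumns]
}

#' @rdname readSampleMetadata
#' @param meta metadata data.frame.
#' @export
writeSampleMetadata <- function(meta, path) {
  utils::write.table(meta[metadataColumns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Quantile-normalize a GEM across samples
#'
#' Every sample's value vector is replaced so that its sorted values equal
#' the across-sample mean of order statistics; within-sample rank order is
#' preserved.  Ties receive the mean of the order-statistic means of the
#' positions they span, which is deterministic and independent of sample
#' order.  The operation is idempotent.
#'
#' @param gem a [GEM-class] with at least one sample.
#' @return the normalized [GEM-class].
#' @examples
#' m <- matrix(c(5, 2, 3, 4, 1, 2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("S1", "S2"), c("t1", "t2", "t3")))
#' exprValues(quantileNormalize(GEM(m)))  # both samples become 4.5 1.5 2.5
#' @export
quantileNormalize <- function(gem) {
  x <- exprValues(gem)
  if (nrow(x) < 1L) stop("need at least one sample")
  sorted <- apply(x, 1L, sort)                     # transcripts x samples
  if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = 1L)
  mu <- rowMeans(sorted)                           # mean order statistics
  cs <- c(0, cumsum(mu))
  out <- x
  for (i in seq_len(nrow(x))) {
    lo <- rank(x[i, ], ties.method = "min")
    hi <- rank(x[i, ], ties.method = "max")
    out[i, ] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  GEM(out)
}

#' Kolmogorov-Smirnov outlier screen over samples
#'
#' Each sample's value distribution is compared by a two-sample KS test
#' against the pooled values of all other samples; samples significant
#' after Bonferroni correction (p < alpha / n_samples) are removed.
#'
#' @param gem a [GEM-class] with at least 3 samples.
#' @param alpha significance level in (0, 1) before Bonferroni correction.
#' @return list with \code{gem} (filtered) and \code{removed} (sample ids).
#' @export
ksOutlierScreen <- function(gem, alpha = 0.01) {
  assertScalar(alpha, "alpha", 0, 1, openLower = TRUE, openUpper = TRUE)
  x <- exprValues(gem)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples")
  p <- vapply(seq_len(n), function(i)
    suppressWarnings(stats::ks.test(x[i, ], as.vector(x[-i, ]))$p.value),
    numeric(1L))
  bad <- which(p < alpha / n)
  removed <- rownames(x)[bad]
  out <- if (length(bad) > 0L) GEM(x[-bad, , drop = FALSE]) else gem
  list(gem = out, removed = removed)
}
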