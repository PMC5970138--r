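#' @import methods
NULL

#' Gene expression matrix
#'
#' Container for a gene expression matrix (GEM) in the package's canonical
#' orientation: samples in rows, transcripts in columns.  On-disk TSV files
#' use the transposed convention (transcripts in rows, one column per
#' sample); [readGem()] and [writeGem()] convert between the two.
#'
#' @slot values numeric matrix, samples x transcripts, non-negative, with
#'   sample ids as rownames and transcript ids as colnames.
#'
#' @seealso [readGem()], [quantileNormalize()], [svdDecompose()]
#' @export
setClass("GEM", representation(values = "matrix"))

setValidity("GEM", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (any(!is.finite(v))) return("values contain NA/NaN/Inf")
  if (any(v < 0)) return("values must be non-negative")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry sample ids (rownames) and transcript ids (colnames)")
  if (anyDuplicated(rownames(v))) return("duplicate sample ids")
  if (anyDuplicated(colnames(v))) return("duplicate transcript ids")
  TRUE
})

#' Construct a GEM from a samples x transcripts matrix
#'
#' @param values numeric matrix, samples x transcripts, with dimnames.
#' @return A [GEM-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("S", 1:3), c("tA", "tB")))
#' GEM(m)
#' @export
GEM <- function(values) {
  if (length(values) == 0L) stop("empty expression matrix")
  storage.mode(values) <- "double"
  new("GEM", values = values)
}

#' @describeIn GEM-class expression values (samples x transcripts matrix)
#' @param gem a [GEM-class] object
#' @export
exprValues <- function(gem) gem@values

#' @describeIn GEM-class sample identifiers
#' @export
sampleIds <- function(gem) rownames(gem@values)

#' @describeIn GEM-class transcript identifiers
#' @export
transcriptIds <- function(gem) colnames(gem@values)

#' @describeIn GEM-class number of samples
#' @export
nSamples <- function(gem) nrow(gem@values)

#' @describeIn GEM-class number of transcripts
#' @export
nTranscripts <- function(gem) ncol(gem@values)

#' @export
setMethod("show", "GEM", function(object) {
  cat(sprintf("GEM: %d samples x %d transcripts\n",
              nrow(object@values), ncol(object@values)))
  cat("  samples:    ", paste(utils::head(rownames(object@values), 4L), collapse = ", "),
      if (nrow(object@values) > 4L) ", ..." else "", "\n", sep = "")
  cat("  transcripts:", paste(utils::head(colnames(object@values), 4L), collapse = ", "),
      if (ncol(object@values) > 4L) ", ..." else "", "\n", sep = "")
})

#' @describeIn GEM-class subset samples (i) and/or transcripts (j)
#' @param x,i,j,...,drop matrix-style subsetting arguments (drop is ignored)
#' @export
setMethod("[", "GEM", function(x, i, j, ..., drop = FALSE) {
  GEM(x@values[i, j, drop = FALSE])
})

#' @export
setMethod("dim", "GEM", function(x) dim(x@values))

#' Thin singular value decomposition of a GEM
#'
#' Holds the factors of \code{X = U diag(S) Vt} for a samples x transcripts
#' matrix X, with singular values sorted in decreasing order and a
#' deterministic sign convention (the largest-magnitude component of each
#' right singular vector is positive).
#'
#' @slot U samples x r matrix of left singular vectors.
#' @slot S numeric vector of r singular values, non-increasing.
#' @slot Vt r x transcripts matrix of right singular vectors (rows).
#' @slot frobNorm Frobenius norm of the decomposed matrix.
#' @export
setClass("SVDFactors",
         representation(U = "matrix", S = "numeric", Vt = "matrix",
                        frobNorm = "numeric"))

setValidity("SVDFactors", function(object) {
  r <- length(object@S)
  if (ncol(object@U) != r || nrow(object@Vt) != r)
    return("inconsistent factor dimensions")
  if (any(object@S < 0)) return("singular values must be non-negative")
  if (is.unsorted(rev(object@S))) return("singular values must be non-increasing")
  TRUE
})

#' @export
setMethod("show", "SVDFactors", function(object) {
  cat(sprintf("SVDFactors: %d samples x %d transcripts, rank %d\n",
              nrow(object@U), ncol(object@Vt), length(object@S)))
  cat("  leading singular values:",
      paste(signif(utils::head(object@S, 5L), 4L), collapse = ", "), "\n")
})

#' DQC evolution trajectory
#'
#' A list of frames, each a samples x dims coordinate matrix.  The first
#' frame is the input configuration; frame t+1 is obtained from frame t by
#' evolving every sample's Gaussian wave packet under the data Hamiltonian
#' and re-centering.
#'
#' @slot frames list of numeric matrices of identical dimension.
#' @slot sigma Gaussian width actually used.
#' @slot mass mass parameter actually used.
#' @slot dt time step per evolution step.
#' @slot normDrift per-frame maximum deviation of any packet's norm from 1
#'   across the frame's steps (unitarity diagnostic).
#' @slot energyDrift per-frame maximum within-frame drift of any packet's
#'   energy expectation (the Hamiltonian is rebuilt between frames, so
#'   energy is only conserved within a frame).
#' @export
setClass("Trajectory",
         representation(frames = "list", sigma = "numeric", mass = "numeric",
                        dt = "numeric", normDrift = "numeric",
                        energyDrift = "numeric"),
         prototype(normDrift = numeric(0), energyDrift = numeric(0)))

setValidity("Trajectory", function(object) {
  if (length(object@frames) == 0L) return("no frames")
  d <- dim(object@frames[[1L]])
  for (f in object@frames) {
    if (!identical(dim(f), d)) return("frames differ in shape")
    if (any(!is.finite(f))) return("non-finite coordinates in a frame")
  }
  TRUE
})

#' @describeIn Trajectory-class number of frames (including the input frame)
#' @param traj a [Trajectory-class]
#' @export
nFrames <- function(traj) length(traj@frames)

#' @describeIn Trajectory-class extract one frame's coordinate matrix
#' @param frame 1-based frame index; frame 1 is the input configuration
#' @export
frameCoords <- function(traj, frame) {
  if (frame < 1L || frame > length(traj@frames)) stop("frame index out of range")
  traj@frames[[frame]]
}

#' @export
setMethod("show", "Trajectory", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("Trajectory: %d frames of %d points in %d dims (sigma=%.4g, mass=%.4g, dt=%.3g)\n",
              length(object@frames), d[1L], d[2L], object@sigma, object@mass, object@dt))
})

#' One layer of iterative DQC feature selection
#'
#' @slot iteration 1-based iteration index.
#' @slot transcripts ordered ids selected at this iteration.
#' @slot perDimension data.frame with one row per contributing SVD dimension:
#'   \code{dimension}, \code{threshold} (smallest selected component
#'   magnitude) and \code{count}.
#' @slot remaining number of transcripts left after removing this layer.
#' @export
setClass("FeatureLayer",
         representation(iteration = "integer", transcripts = "character",
                        perDimension = "data.frame", remaining = "integer"))

#' @export
setMethod("show", "FeatureLayer", function(object) {
  cat(sprintf("FeatureLayer %d: %d transcripts from %d dimension(s); %d remaining\n",
              object@iteration, length(object@transcripts),
              nrow(object@perDimension), object@remaining))
})

#' Consensus of an embedding/clustering ensemble
#'
#' @slot labelMatrix embeddings x samples integer matrix of per-embedding
#'   HDBSCAN labels; -1 marks noise.
#' @slot consensusLabels named integer vector of per-sample consensus
#'   cluster ids (1-based).
#' @slot coAssociation samples x samples matrix of pairwise same-cluster
#'   agreement fractions.
#' @export
setClass("ConsensusResult",
         representation(labelMatrix = "matrix", consensusLabels = "integer",
                        coAssociation = "matrix"))

setValidity("ConsensusResult", function(object) {
  A <- object@coAssociation
  if (nrow(A) != ncol(A)) return("coAssociation must be square")
  if (any(A < -1e-12) || any(A > 1 + 1e-12)) return("coAssociation outside [0,1]")
  if (max(abs(A - t(A))) > 1e-12) return("coAssociation not symmetric")
  if (max(abs(diag(A) - 1)) > 1e-12) return("coAssociation diagonal must be 1")
  if (length(object@consensusLabels) != nrow(A))
    return("label length mismatch")
  TRUE
})

#' @export
setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d samples, %d embeddings, %d consensus clusters\n",
              ncol(object@labelMatrix), nrow(object@labelMatrix),
              length(unique(object@consensusLabels))))
})

#' Annotation map for term over-representation
#'
#' @slot terms named list; each element is a character vector of member
#'   transcript ids, names are term ids.
#' @slot termNames named character vector of human-readable descriptions.
#' @slot background character vector: the annotation universe.
#' @export
setClass("AnnotationMap",
         representation(terms = "list", termNames = "character",
                        background = "character"))

setValidity("AnnotationMap", function(object) {
  if (length(object@terms) == 0L) return("no terms")
  for (tm in names(object@terms)) {
    m <- object@terms[[tm]]
    if (length(m) == 0L) return(sprintf("term '%s' has no members", tm))
    if (!all(m %in% object@background))
      return(sprintf("term '%s' has members outside the background", tm))
  }
  TRUE
})

#' @export
setMethod("show", "AnnotationMap", function(object) {
  cat(sprintf("AnnotationMap: %d terms over a background of %d transcripts\n",
              length(object@terms), length(object@background)))
})
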