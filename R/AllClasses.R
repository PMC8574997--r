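#' @import methods
#' @importFrom stats sd var cor quantile rnorm runif rbinom qt prcomp
#'   shapiro.test aggregate predict coef lm hclust as.dist cutree dist
#'   setNames model.matrix
#' @importFrom utils head read.csv write.csv combn packageVersion
#' @importFrom tools md5sum
NULL

#' FingerprintMatrix: compounds-by-bits fingerprint container
#'
#' Holds one fingerprint matrix for a set of compounds, together with the
#' taxonomy used throughout the package: rule-based fingerprints are binary
#' (folded circular "Morgan" or path-based "topological" bits), data-driven
#' fingerprints are continuous (graph-autoencoder or sequence-VAE latents).
#' Rows are compounds (rownames are compound identifiers), columns are bits.
#'
#' @slot values numeric matrix, m compounds x nBits; rownames are compound ids.
#' @slot dataFormat `"binary"` or `"continuous"`.
#' @slot fpType `"rule"` or `"data"`.
#' @slot fpSubtype one of `"circular-2D"`, `"circular-3D"`, `"path"`,
#'   `"graph"`, `"sequence"`.
#' @slot nBits integer, number of bits (columns).
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
  representation(
    values = "matrix",
    dataFormat = "character",
    fpType = "character",
    fpSubtype = "character",
    nBits = "integer"
  )
)

setValidity("FingerprintMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  if (is.null(rownames(v))) msg <- c(msg, "values must have compound ids as rownames")
  else if (anyDuplicated(rownames(v))) msg <- c(msg, "compound ids must be unique")
  if (!object@dataFormat %in% c("binary", "continuous"))
    msg <- c(msg, "dataFormat must be 'binary' or 'continuous'")
  if (!object@fpType %in% c("rule", "data"))
    msg <- c(msg, "fpType must be 'rule' or 'data'")
  if (!object@fpSubtype %in% c("circular-2D", "circular-3D", "path", "graph", "sequence"))
    msg <- c(msg, "unknown fpSubtype")
  if (object@nBits != ncol(v)) msg <- c(msg, "nBits must equal ncol(values)")
  if (object@dataFormat == "binary" && length(v) && !all(v %in% c(0, 1)))
    msg <- c(msg, "binary fingerprints may contain only 0/1")
  if (length(msg)) msg else TRUE
})

#' Construct a FingerprintMatrix
#'
#' @param values numeric matrix with compound ids as rownames.
#' @param dataFormat "binary" or "continuous".
#' @param fpType "rule" or "data".
#' @param fpSubtype fingerprint subtype tag.
#' @return A [FingerprintMatrix-class] object.
#' @export
FingerprintMatrix <- function(values, dataFormat, fpType, fpSubtype) {
  new("FingerprintMatrix", values = as.matrix(values), dataFormat = dataFormat,
      fpType = fpType, fpSubtype = fpSubtype, nBits = ncol(values))
}

#' MolecularGraph: adjacency and node features of one molecule
#'
#' The graph view of a standardized molecule: binary symmetric adjacency
#' (bond presence only), the self-loop degree-normalized adjacency
#' D^-1/2 (A + I) D^-1/2 used by the graph autoencoder, and the 54-column
#' one-hot node feature matrix (atom type, degree, formal charge, chirality,
#' aromaticity).
#'
#' @slot smiles standardized SMILES the graph was built from.
#' @slot adjacency binary symmetric |V| x |V| matrix, zero diagonal.
#' @slot adjNorm normalized adjacency with self-loops.
#' @slot nodeFeatures |V| x 54 one-hot feature matrix.
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(
    smiles = "character",
    adjacency = "matrix",
    adjNorm = "matrix",
    nodeFeatures = "matrix"
  )
)

setValidity("MolecularGraph", function(object) {
  msg <- character(0)
  A <- object@adjacency
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (nrow(A) >= 1) {
    if (any(A != t(A))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
  }
  if (nrow(object@adjNorm) != nrow(A)) msg <- c(msg, "adjNorm size mismatch")
  if (nrow(object@nodeFeatures) != nrow(A)) msg <- c(msg, "nodeFeatures row mismatch")
  if (ncol(object@nodeFeatures) != 54L) msg <- c(msg, "nodeFeatures must have 54 columns")
  if (length(msg)) msg else TRUE
})

#' SimilarityResult: HSIC/CKA comparison of two fingerprint matrices
#'
#' @slot hsicXY,hsicXX,hsicYY raw HSIC values (cross and self terms).
#' @slot cka centered kernel alignment in [0, 1].
#' @slot mode `"feature"` or `"sample"` (which kernel space was used).
#' @slot estimator `"biased"` or `"unbiased"`.
#' @exportClass SimilarityResult
setClass("SimilarityResult",
  representation(
    hsicXY = "numeric",
    hsicXX = "numeric",
    hsicYY = "numeric",
    cka = "numeric",
    mode = "character",
    estimator = "character"
  )
)

setValidity("SimilarityResult", function(object) {
  msg <- character(0)
  if (object@cka < -1e-9 || object@cka > 1 + 1e-9)
    msg <- c(msg, "cka must lie in [0, 1] (1e-9 tolerance)")
  if (!object@mode %in% c("feature", "sample")) msg <- c(msg, "bad mode")
  if (!object@estimator %in% c("biased", "unbiased")) msg <- c(msg, "bad estimator")
  if (length(msg)) msg else TRUE
})
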