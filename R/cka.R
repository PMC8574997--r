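## Linear-kernel HSIC and centered kernel alignment between fingerprint
## matrices of arbitrary widths and data types. Binary fingerprints are cast
## to reals and treated exactly like continuous ones.

asDataMatrix <- function(X) {
  if (is(X, "FingerprintMatrix")) X <- fpValues(X)
  as.matrix(X) * 1
}

#' Center the columns of a data matrix
#'
#' Subtracts each column's mean; idempotent. Requires at least two rows.
#'
#' @param X numeric matrix (or [FingerprintMatrix-class]) with m >= 2 rows.
#' @return matrix with zero column means.
#' @export
centerColumns <- function(X) {
  X <- asDataMatrix(X)
  if (nrow(X) < 2L) stop("centering requires at least 2 rows")
  sweep(X, 2, colMeans(X))
}

#' Linear-kernel HSIC in feature space
#'
#' The squared Frobenius norm of the feature cross-product, `||Y^T X||_F^2`.
#' For centered inputs this equals the sample-space trace form (see
#' [hsicSample()]); the feature form is the efficient choice when compounds
#' outnumber bits.
#'
#' @param X,Y centered matrices with the same row count.
#' @return non-negative scalar, symmetric in X and Y.
#' @export
hsicFeature <- function(X, Y) {
  X <- asDataMatrix(X); Y <- asDataMatrix(Y)
  if (nrow(X) != nrow(Y)) stop("row-count (compound) mismatch")
  sum(crossprod(Y, X)^2)
}

#' Linear-kernel HSIC in sample space
#'
#' The Gram-matrix trace form `trace(X X^T Y Y^T)`, computed literally from
#' the two m x m Gram matrices. Equals [hsicFeature()] for centered inputs
#' under the linear kernel.
#'
#' @param X,Y centered matrices with the same row count.
#' @return non-negative scalar.
#' @export
hsicSample <- function(X, Y) {
  X <- asDataMatrix(X); Y <- asDataMatrix(Y)
  if (nrow(X) != nrow(Y)) stop("row-count (compound) mismatch")
  Kx <- tcrossprod(X); Ky <- tcrossprod(Y)
  sum(Kx * Ky)   # trace(Kx Ky) for symmetric Kx, Ky
}

#' Unbiased HSIC estimator on Gram matrices
#'
#' The standard U-statistic estimator (Song et al.): diagonals zeroed, the
#' three-term combination with prefactor 1/(m(m-3)). Unbiased for
#' independent data (expectation 0) and hence possibly slightly negative on
#' finite samples. Requires m >= 4.
#'
#' @param Kx,Ky m x m symmetric Gram matrices.
#' @return scalar estimate (may be negative).
#' @export
hsicUnbiased <- function(Kx, Ky) {
  m <- nrow(Kx)
  if (m < 4L)
    stop("the unbiased HSIC estimator requires at least m = 4 samples")
  stopifnot(ncol(Kx) == m, all(dim(Ky) == m))
  Kt <- Kx; diag(Kt) <- 0
  Lt <- Ky; diag(Lt) <- 0
  sK <- colSums(Kt); sL <- colSums(Lt)
  term1 <- sum(Kt * Lt)
  term2 <- sum(sK) * sum(sL) / ((m - 1) * (m - 2))
  term3 <- 2 / (m - 2) * sum(sK * sL)
  (term1 + term2 - term3) / (m * (m - 3))
}

#' Centered kernel alignment between two fingerprint matrices
#'
#' `CKA = HSIC(X,Y) / sqrt(HSIC(X,X) * HSIC(Y,Y))` under the linear kernel,
#' after column centering. Ranges in [0, 1]; equals 1 for a matrix against
#' itself (and under isotropic scaling or orthogonal rotation of either
#' argument). The default estimator is the unbiased U-statistic on Gram
#' matrices; the biased (plug-in) estimator supports both the feature- and
#' sample-space computation, chosen by the feature-vs-sample rule (feature
#' space when compounds outnumber bits) when `mode = "auto"`.
#'
#' A slightly negative unbiased cross-HSIC is clamped to 0 in the ratio (raw
#' values are retained in the result); a constant (zero after centering)
#' argument has no defined similarity and raises an error.
#'
#' @param X,Y matrices or [FingerprintMatrix-class] objects over the same
#'   compounds (same row count and order).
#' @param estimator `"unbiased"` (default) or `"biased"`.
#' @param mode `"auto"`, `"feature"` or `"sample"` (biased estimator only).
#' @return a [SimilarityResult-class] object.
#' @export
cka <- function(X, Y, estimator = c("unbiased", "biased"), mode = "auto") {
  estimator <- match.arg(estimator)
  Xc <- centerColumns(X); Yc <- centerColumns(Y)
  if (nrow(Xc) != nrow(Yc)) stop("row-count (compound) mismatch")
  if (all(Xc == 0) || all(Yc == 0))
    stop("undefined similarity: an argument is constant (zero after centering)")
  if (estimator == "unbiased") {
    Kx <- tcrossprod(Xc); Ky <- tcrossprod(Yc)
    hXY <- hsicUnbiased(Kx, Ky)
    hXX <- hsicUnbiased(Kx, Kx)
    hYY <- hsicUnbiased(Ky, Ky)
    usedMode <- "sample"
  } else {
    m <- nrow(Xc)
    if (mode == "auto")
      mode <- if (m > max(ncol(Xc), ncol(Yc))) "feature" else "sample"
    fn <- if (mode == "feature") hsicFeature else hsicSample
    hXY <- fn(Xc, Yc); hXX <- fn(Xc, Xc); hYY <- fn(Yc, Yc)
    usedMode <- mode
  }
  if (hXX <= 0 || hYY <= 0)
    stop("undefined similarity: non-positive self-HSIC")
  val <- max(hXY, 0) / sqrt(hXX * hYY)
  new("SimilarityResult", hsicXY = hXY, hsicXX = hXX, hsicYY = hYY,
      cka = min(val, 1), mode = usedMode, estimator = estimator)
}

#' Pairwise CKA similarity across fingerprint types
#'
#' Computes the symmetric CKA matrix over a list of fingerprint matrices
#' that share compounds (aligned ids and row order), the corresponding
#' distance matrix `1 - CKA`, and an average-linkage hierarchical-clustering
#' ordering for heatmap display.
#'
#' @param fps named list of [FingerprintMatrix-class] objects (or plain
#'   matrices with identical rownames).
#' @param estimator passed to [cka()].
#' @return list with `similarity` (unit diagonal), `distance`, `order`
#'   (display permutation) and `hclust`.
#' @export
pairwiseCKA <- function(fps, estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  stopifnot(length(fps) >= 2L)
  nm <- names(fps)
  if (is.null(nm)) nm <- paste0("fp", seq_along(fps))
  ids <- lapply(fps, function(f) rownames(asDataMatrix(f)))
  ref <- ids[[1]]
  for (i in seq_along(ids)) {
    if (!identical(ids[[i]], ref)) {
      bad <- union(setdiff(ids[[i]], ref), setdiff(ref, ids[[i]]))
      stop("compound-set mismatch between fingerprints '", nm[1], "' and '",
           nm[i], "'",
           if (length(bad)) paste0(": differing ids ",
                                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  k <- length(fps)
  S <- diag(1, k); dimnames(S) <- list(nm, nm)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    v <- ckaValue(cka(fps[[i]], fps[[j]], estimator = estimator))
    S[i, j] <- v; S[j, i] <- v
  }
  D <- 1 - S
  hc <- hclust(as.dist(D), method = "average")
  list(similarity = S, distance = D, order = hc$order, hclust = hc)
}
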