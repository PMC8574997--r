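## Class-based clustering evaluation: z-score / PCA / PLS preprocessing,
## one-versus-all linear discriminant projections, Silhouette and the
## variance ratio criterion, min-max scaled and ranked across fingerprints.

#' Z-score normalize the columns of a matrix
#'
#' Column means 0 and population (n-denominator) standard deviations 1.
#' Constant columns carry no information and are dropped with a warning.
#'
#' @param X numeric matrix or [FingerprintMatrix-class].
#' @return normalized matrix (possibly fewer columns).
#' @export
zscoreNormalize <- function(X) {
  X <- asDataMatrix(X)
  sds <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  if (all(sds == 0)) stop("all columns constant: cannot z-score")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant column(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  sweep(sweep(X, 2, colMeans(X)), 2, sds, `/`)
}

#' PCA reduction to >0.95 cumulative explained variance
#'
#' Projects a z-scored matrix onto the smallest number of leading principal
#' components whose cumulative explained-variance ratio exceeds the
#' threshold.
#'
#' @param X z-scored matrix.
#' @param varThreshold cumulative variance threshold (0.95).
#' @return score matrix (m x nComponents).
#' @export
pcaReduce <- function(X, varThreshold = 0.95) {
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- cumsum(ev) / sum(ev)
  ncomp <- which(ratio > varThreshold)[1]
  pc$x[, seq_len(ncomp), drop = FALSE]
}

#' PLS reduction with class labels as targets
#'
#' Partial least squares scores with the one-hot class labels as the
#' multivariate response. The default component count is K - 1, matching
#' the discriminative dimensionality of K classes.
#'
#' @param X z-scored matrix.
#' @param labels class labels aligned to rows.
#' @param nComponents number of PLS components (default K - 1).
#' @return score matrix (m x nComponents).
#' @export
plsReduce <- function(X, labels, nComponents = NULL) {
  labels <- as.factor(labels)
  K <- nlevels(labels)
  if (is.null(nComponents)) nComponents <- K - 1L
  if (nComponents > min(dim(X)))
    stop("nComponents exceeds min(m, n)")
  Yd <- stats::model.matrix(~ labels - 1)
  fit <- mixOmics::pls(X, Yd, ncomp = nComponents, scale = FALSE)
  as.matrix(fit$variates$X)
}

fisherDirection <- function(X, y) {
  ## binary Fisher discriminant with automatic ridge on a singular
  ## within-class scatter
  X1 <- X[y, , drop = FALSE]; X0 <- X[!y, , drop = FALSE]
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  S <- crossprod(sweep(X1, 2, m1)) + crossprod(sweep(X0, 2, m0))
  w <- tryCatch(solve(S, m1 - m0), error = function(e) NULL)
  if (is.null(w)) {
    warning("singular within-class scatter: ridge-regularized")
    lam <- 1e-6 * mean(diag(S)) + 1e-12
    w <- solve(S + diag(lam, ncol(S)), m1 - m0)
  }
  w
}

#' One-versus-all linear discriminant projections
#'
#' For each class k fits a binary (k versus rest) linear discriminant and
#' projects all points onto its axis, yielding K one-dimensional
#' projections. A singular within-class scatter is ridge-regularized with a
#' warning.
#'
#' @param X feature matrix (reduce first if features approach m - 2).
#' @param labels class labels, each class with >= 2 members.
#' @return list of K numeric projection vectors, named by class.
#' @export
ldaOneVsAll <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (any(table(labels) < 2L)) stop("every class needs >= 2 members")
  if (ncol(X) > nrow(X) - 2L)
    warning("more features than m - 2; consider dimensionality reduction")
  out <- lapply(levels(labels), function(k) {
    as.numeric(X %*% fisherDirection(X, labels == k))
  })
  names(out) <- levels(labels)
  out
}

#' Mean Silhouette score of a 1D projection
#'
#' For each point i, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where a(i) is
#' the mean distance to the other members of its own cluster and b(i) the
#' smallest mean distance to another cluster. Euclidean distance on the
#' projection; singleton-cluster points (and ties with max(a,b) = 0) score 0.
#'
#' @param projection numeric vector.
#' @param labels cluster labels (>= 2 clusters).
#' @return mean silhouette in [-1, 1].
#' @export
silhouetteMean <- function(projection, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("silhouette requires >= 2 clusters")
  n <- length(projection)
  stopifnot(length(labels) == n)
  D <- abs(outer(projection, projection, `-`))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1L)
    b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                    function(k) mean(D[i, labels == k]), numeric(1)))
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Variance ratio criterion (Calinski-Harabasz index)
#'
#' `[SSB / (K - 1)] / [SSW / (n - K)]`: between- over within-cluster
#' variation adjusted by the number of clusters. A zero within-cluster sum
#' of squares is reported as `Inf` with a `"perfect"` attribute flag.
#'
#' @param projection numeric vector.
#' @param labels cluster labels (K >= 2, n > K).
#' @return non-negative scalar (possibly `Inf`).
#' @export
vrc <- function(projection, labels) {
  labels <- as.factor(labels)
  K <- nlevels(labels); n <- length(projection)
  stopifnot(K >= 2L, n > K)
  gm <- mean(projection)
  ssb <- 0; ssw <- 0
  for (k in levels(labels)) {
    xk <- projection[labels == k]
    ssb <- ssb + length(xk) * (mean(xk) - gm)^2
    ssw <- ssw + sum((xk - mean(xk))^2)
  }
  if (ssw == 0) return(structure(Inf, perfect = TRUE))
  (ssb / (K - 1)) / (ssw / (n - K))
}

## average one-vs-all silhouette and VRC over the K binary problems
ovaScores <- function(X, labels) {
  projs <- ldaOneVsAll(X, labels)
  labels <- as.factor(labels)
  sil <- mean(vapply(names(projs), function(k) {
    silhouetteMean(projs[[k]], factor(labels == k))
  }, numeric(1)))
  vr <- mean(vapply(names(projs), function(k) {
    as.numeric(vrc(projs[[k]], factor(labels == k)))
  }, numeric(1)))
  c(silhouette = sil, vrc = vr)
}

#' Clustering score table across fingerprints
#'
#' Evaluates every fingerprint under three preprocessing regimes (z-score;
#' z-score + PCA at >0.95 variance; z-score + PLS with labels as targets),
#' scoring each by the mean one-versus-all silhouette and VRC (averaged
#' over the K binary problems). Raw scores are min-max scaled to [0, 1] per
#' metric within each regime (best fingerprint 1, worst 0), and fingerprints
#' are ranked by the z-score-regime scaled scores (silhouette, VRC as
#' tie-break).
#'
#' @param fps named list (>= 2) of [FingerprintMatrix-class] objects or
#'   matrices over the same compounds.
#' @param labels class labels aligned to the fingerprint rows (K classes,
#'   each with >= 2 members).
#' @param plsComponents PLS component count (default K - 1).
#' @return data.frame: fingerprint, preprocessing, silhouette_raw, vrc_raw,
#'   silhouette_scaled, vrc_scaled, rank.
#' @export
scoreTable <- function(fps, labels, plsComponents = NULL) {
  stopifnot(length(fps) >= 2L, !is.null(names(fps)))
  labels <- as.factor(labels)
  regimes <- c("z", "z+PCA", "z+PLS")
  rows <- list()
  for (nm in names(fps)) {
    Xz <- zscoreNormalize(fps[[nm]])
    stopifnot(nrow(Xz) == length(labels))
    for (reg in regimes) {
      Xr <- switch(reg,
                   "z" = Xz,
                   "z+PCA" = pcaReduce(Xz),
                   "z+PLS" = plsReduce(Xz, labels, plsComponents))
      sc <- ovaScores(Xr, labels)
      rows[[length(rows) + 1L]] <- data.frame(
        fingerprint = nm, preprocessing = reg,
        silhouette_raw = sc[["silhouette"]], vrc_raw = sc[["vrc"]],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  minmax <- function(x) {
    if (max(x) == min(x)) return(rep(1, length(x)))
    (x - min(x)) / (max(x) - min(x))
  }
  res$silhouette_scaled <- NA_real_; res$vrc_scaled <- NA_real_
  for (reg in regimes) {
    idx <- res$preprocessing == reg
    res$silhouette_scaled[idx] <- minmax(res$silhouette_raw[idx])
    res$vrc_scaled[idx] <- minmax(res$vrc_raw[idx])
  }
  zIdx <- res$preprocessing == "z"
  zi <- res[zIdx, ]
  ord <- order(-zi$silhouette_scaled, -zi$vrc_scaled)
  rk <- integer(nrow(zi)); rk[ord] <- seq_len(nrow(zi))
  res$rank <- rk[match(res$fingerprint, zi$fingerprint)]
  res
}
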