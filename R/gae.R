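## Graph autoencoder on molecular graphs, authored in base R matrix ops.
##
## Encoder: seven graph-convolution layers, each a sum aggregation over the
## self-loop-normalized adjacency (A_norm %*% H %*% W) followed by ReLU.
## Decoder: sigmoid of the embedding Gram matrix Z Z^T (dropout 0.1 on the
## logits during training). Loss: elementwise binary cross-entropy with the
## entries of A_norm as soft targets. Gradients are hand-derived; the
## optimizer is Adam with halve-on-plateau learning-rate decay.

#' Graph autoencoder configuration
#'
#' @param nLayers number of graph-convolution layers (7).
#' @param embeddingDim output embedding width; the 64-bit fingerprint
#'   construction (3 pooled blocks + 16 singular values) requires 16.
#' @param hiddenDims widths of the intermediate layers (length nLayers - 1);
#'   default geometric interpolation between the 54 input features and the
#'   embedding.
#' @param dropout decoder logit dropout rate during training.
#' @param lrInit,lrFloor initial learning rate and halting floor.
#' @param epochs training epochs per fold.
#' @param folds number of cross-validation folds in the training loop.
#' @param batchSize molecules per gradient step.
#' @param target `"anorm"` (soft targets, the normalized adjacency itself)
#'   or `"binary"` (the 0/1 self-loop adjacency).
#' @param seed RNG seed controlling init, dropout and fold shuffling.
#' @return list of class `gaeConfig`.
#' @export
gaeConfig <- function(nLayers = 7L, embeddingDim = 16L,
                      hiddenDims = c(48L, 40L, 36L, 32L, 24L, 20L),
                      dropout = 0.1, lrInit = 1e-3, lrFloor = 1e-6,
                      epochs = 40L, folds = 5L, batchSize = 8L,
                      target = c("anorm", "binary"), seed = 1L) {
  target <- match.arg(target)
  stopifnot(embeddingDim >= 16L, lrFloor < lrInit,
            length(hiddenDims) == nLayers - 1L)
  structure(list(nLayers = nLayers, embeddingDim = embeddingDim,
                 hiddenDims = hiddenDims, dropout = dropout,
                 lrInit = lrInit, lrFloor = lrFloor, epochs = epochs,
                 folds = folds, batchSize = batchSize, target = target,
                 seed = seed),
            class = "gaeConfig")
}

xavierUniform <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

#' Initialize GAE weights
#'
#' @param config a [gaeConfig()].
#' @param inputDim node feature width (54).
#' @return list of `nLayers` weight matrices (Xavier uniform).
#' @export
gaeInitWeights <- function(config, inputDim = 54L) {
  dims <- c(inputDim, config$hiddenDims, config$embeddingDim)
  lapply(seq_len(config$nLayers),
         function(l) xavierUniform(dims[l], dims[l + 1L]))
}

graphParts <- function(graph) {
  if (is(graph, "MolecularGraph"))
    list(An = adjacencyNorm(graph), X = nodeFeatures(graph))
  else list(An = graph$An, X = graph$X)
}

#' Encode a molecular graph into its embedding matrix
#'
#' Applies the seven-layer graph convolution stack; deterministic given the
#' weights (no dropout in the encoder). Permutation-equivariant: relabeling
#' the nodes permutes the embedding rows identically.
#'
#' @param graph a [MolecularGraph-class] (or list with `An`, `X`).
#' @param weights weight list from [gaeInitWeights()] or [trainGAE()].
#' @return |V| x embeddingDim matrix.
#' @export
gaeEncode <- function(graph, weights) {
  p <- graphParts(graph)
  H <- p$X
  for (W in weights) {
    if (ncol(H) != nrow(W))
      stop("config error: weight shape ", nrow(W), "x", ncol(W),
           " does not accept input of width ", ncol(H))
    H <- pmax(p$An %*% H %*% W, 0)
  }
  H
}

#' Decode an embedding matrix into edge probabilities
#'
#' Sigmoid of the embedding Gram matrix `Z Z^T`; during training a dropout
#' mask is applied to the logits.
#'
#' @param Z embedding matrix.
#' @param training logical; apply dropout when TRUE.
#' @param dropout dropout rate used when training.
#' @return |V| x |V| matrix with entries in (0, 1); symmetric at inference.
#' @export
gaeDecode <- function(Z, training = FALSE, dropout = 0.1) {
  stopifnot(all(is.finite(Z)))
  Q <- Z %*% t(Z)
  if (training && dropout > 0) {
    M <- matrix(rbinom(length(Q), 1L, 1 - dropout), nrow(Q)) / (1 - dropout)
    Q <- Q * M
  }
  1 / (1 + exp(-Q))
}

#' Binary cross-entropy reconstruction loss with soft targets
#'
#' Mean elementwise cross-entropy between the reconstruction and the
#' (possibly soft, in [0,1]) target matrix. Zero exactly when the
#' reconstruction equals a binary target; equal to the target entropy at a
#' perfect reconstruction of soft targets.
#'
#' @param recon reconstruction in (0, 1).
#' @param target matrix of the same shape with entries in [0, 1].
#' @return non-negative scalar.
#' @export
gaeLoss <- function(recon, target) {
  if (!all(dim(recon) == dim(target)))
    stop("shape mismatch between reconstruction and target")
  eps <- 1e-12
  p <- pmin(pmax(recon, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

## forward with caches, returns loss + gradient list for one molecule
gaeGrad <- function(An, X, target, weights, dropout) {
  L <- length(weights)
  Hs <- vector("list", L + 1L); Hs[[1L]] <- X
  pre <- vector("list", L)
  for (l in seq_len(L)) {
    pre[[l]] <- An %*% Hs[[l]] %*% weights[[l]]
    Hs[[l + 1L]] <- pmax(pre[[l]], 0)
  }
  Z <- Hs[[L + 1L]]
  Q <- Z %*% t(Z)
  if (dropout > 0) {
    M <- matrix(rbinom(length(Q), 1L, 1 - dropout), nrow(Q)) / (1 - dropout)
  } else M <- 1
  P <- 1 / (1 + exp(-(Q * M)))
  loss <- gaeLoss(P, target)
  N <- length(Q)
  dQ <- ((P - target) / N) * M
  dH <- (dQ + t(dQ)) %*% Z
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dPre <- dH * (pre[[l]] > 0)
    grads[[l]] <- t(An %*% Hs[[l]]) %*% dPre
    if (l > 1L) dH <- An %*% dPre %*% t(weights[[l]])
  }
  list(loss = loss, grads = grads)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * grads[[i]]
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * grads[[i]]^2
    mh <- state$m[[i]] / (1 - b1^state$t)
    vh <- state$v[[i]] / (1 - b2^state$t)
    params[[i]] <- params[[i]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Train the graph autoencoder
#'
#' Runs the k-fold training loop: the molecule set is shuffled and split
#' into `folds` folds; the model (one set of weights, carried across folds)
#' is trained for `epochs` epochs on each fold's training portion with Adam.
#' The learning rate is halved whenever the epoch loss fails to improve
#' (patience 1) and training halts once it reaches the floor or the loss
#' reaches zero. Fully reproducible under the config seed.
#'
#' @param graphs list of [MolecularGraph-class] objects (>= 2).
#' @param config a [gaeConfig()].
#' @return list with `weights`, `log` (data.frame: fold, epoch, lr, loss),
#'   and `config`.
#' @export
trainGAE <- function(graphs, config = gaeConfig()) {
  stopifnot(length(graphs) >= 2L)
  set.seed(config$seed)
  weights <- gaeInitWeights(config)
  parts <- lapply(graphs, graphParts)
  targets <- lapply(parts, function(p) {
    if (config$target == "anorm") p$An else (p$An > 0) * 1
  })
  n <- length(graphs)
  foldId <- sample(rep_len(seq_len(config$folds), n))
  opt <- adamInit(weights)
  lr <- config$lrInit
  log <- list()
  best <- Inf
  halted <- FALSE
  for (f in seq_len(config$folds)) {
    trainIdx <- if (config$folds > 1L) which(foldId != f) else seq_len(n)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(trainIdx)
      epochLoss <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), by = config$batchSize)) {
        idx <- ord[start:min(start + config$batchSize - 1L, length(ord))]
        acc <- NULL; bl <- 0
        for (i in idx) {
          g <- gaeGrad(parts[[i]]$An, parts[[i]]$X, targets[[i]], weights,
                       config$dropout)
          bl <- bl + g$loss
          acc <- if (is.null(acc)) g$grads
                 else Map(`+`, acc, g$grads)
        }
        acc <- lapply(acc, `/`, length(idx))
        bl <- bl / length(idx)
        if (!is.finite(bl))
          stop("GAE training diverged (non-finite loss) at fold ", f,
               " epoch ", ep)
        st <- adamStep(weights, acc, opt, lr)
        weights <- st$params; opt <- st$state
        epochLoss <- epochLoss + bl; nb <- nb + 1L
      }
      epochLoss <- epochLoss / nb
      log[[length(log) + 1L]] <- data.frame(fold = f, epoch = ep, lr = lr,
                                            loss = epochLoss)
      if (epochLoss >= best) lr <- lr / 2
      else best <- epochLoss
      if (lr <= config$lrFloor || epochLoss == 0) { halted <- TRUE; break }
    }
    if (halted) break
  }
  list(weights = weights, log = do.call(rbind, log), config = config)
}

#' Singular-value fingerprint (16 bits) of an embedding matrix
#'
#' The descending singular values of the molecule's embedding matrix,
#' truncated/zero-padded to length 16. Motivated by the Ky Fan k-norm: the
#' leading singular values summarize the embedding in a node-order-invariant
#' way.
#'
#' @param Z |V| x embeddingDim embedding matrix.
#' @return non-negative numeric vector of length 16.
#' @export
gaeFingerprint16 <- function(Z) {
  Z <- as.matrix(Z)
  stopifnot(all(is.finite(Z)))
  d <- svd(Z, nu = 0, nv = 0)$d
  d <- sort(d, decreasing = TRUE)
  out <- numeric(16L)
  k <- min(16L, length(d))
  out[seq_len(k)] <- d[seq_len(k)]
  out
}

#' Pooled singular-value fingerprint (64 bits)
#'
#' Concatenation of the column-wise average-, min- and max-pooled embedding
#' with the 16-bit singular-value fingerprint, in that order.
#'
#' @param Z |V| x 16 embedding matrix.
#' @return numeric vector of length 64.
#' @export
gaeFingerprint64 <- function(Z) {
  Z <- as.matrix(Z)
  stopifnot(ncol(Z) == 16L)
  c(colMeans(Z), apply(Z, 2, min), apply(Z, 2, max), gaeFingerprint16(Z))
}

#' GAE fingerprints for a set of molecules
#'
#' @param graphs named list of [MolecularGraph-class] objects.
#' @param weights trained (or fixed) GAE weights.
#' @param variant `"gae16"` or `"gae64"`.
#' @param ids compound ids (default names of `graphs`).
#' @return a [FingerprintMatrix-class] (continuous, graph subtype).
#' @export
gaeFingerprintMatrix <- function(graphs, weights, variant = c("gae16", "gae64"),
                                 ids = names(graphs)) {
  variant <- match.arg(variant)
  if (is.null(ids)) ids <- paste0("mol", seq_along(graphs))
  fn <- if (variant == "gae16") gaeFingerprint16 else gaeFingerprint64
  nb <- if (variant == "gae16") 16L else 64L
  vals <- t(vapply(graphs, function(g) fn(gaeEncode(g, weights)), numeric(nb)))
  rownames(vals) <- ids
  FingerprintMatrix(vals, "continuous", "data", "graph")
}
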