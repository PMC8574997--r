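## SMILES variational autoencoder, authored in base R with hand-derived
## backpropagation.
##
## Encoder: one-hot characters -> three 1D convolutions (widths 9, 9, 10,
## SELU) -> dense heads for the posterior mean and log-variance.
## Decoder: the latent vector, repeated at every timestep, drives a stack of
## three GRU layers followed by a time-distributed softmax over the
## vocabulary. Loss: equally weighted binary cross-entropy (reconstruction)
## and Kullback-Leibler divergence to the standard-normal prior.
## Weights: Xavier uniform. Optimizer: Adam with halve-on-plateau decay.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
seluGrad <- function(x) SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
sigm <- function(x) 1 / (1 + exp(-x))

#' Build a SMILES character vocabulary
#'
#' Unique characters of the corpus in sorted order, with the pad token
#' (a space, which cannot occur in SMILES) reserved at index 1.
#'
#' @param corpus character vector of SMILES strings.
#' @return character vector; element 1 is the pad token.
#' @export
vaeVocab <- function(corpus) {
  chars <- sort(unique(unlist(strsplit(corpus, ""))))
  chars <- setdiff(chars, " ")
  c(" ", chars)
}

smilesToIdx <- function(smiles, vocab, maxLen) {
  n <- nchar(smiles)
  if (any(n > maxLen))
    stop("SMILES longer than maxLen = ", maxLen,
         " (should have been length-filtered): '",
         smiles[which(n > maxLen)[1]], "'")
  idx <- matrix(1L, length(smiles), maxLen)
  for (i in seq_along(smiles)) {
    ch <- strsplit(smiles[i], "")[[1]]
    j <- match(ch, vocab)
    if (anyNA(j)) {
      warning("unknown character(s) ", paste(unique(ch[is.na(j)]), collapse = ""),
              " mapped to the pad slot")
      j[is.na(j)] <- 1L
    }
    if (length(j)) idx[i, seq_along(j)] <- j
  }
  idx
}

#' One-hot encode a SMILES string
#'
#' @param smiles a single SMILES string (length <= `maxLen`).
#' @param vocab vocabulary from [vaeVocab()]; index 1 is the pad token.
#' @param maxLen padded length (140 by default).
#' @return `maxLen` x `length(vocab)` binary matrix; one active column per
#'   row, pad columns beyond the string.
#' @export
smilesOnehot <- function(smiles, vocab, maxLen = 140L) {
  idx <- smilesToIdx(smiles, vocab, maxLen)[1L, ]
  M <- matrix(0, maxLen, length(vocab))
  M[cbind(seq_len(maxLen), idx)] <- 1
  M
}

#' SMILES VAE configuration
#'
#' Defaults follow the reference architecture (three convolutions of widths
#' 9, 9, 10 with SELU; three GRU layers of hidden width 501; 140-character
#' input). `latentDim` must be 16 or 256. Desk-scale runs may shrink
#' `maxLen` and `gruHidden`.
#'
#' @param latentDim latent width, 16 or 256.
#' @param maxLen padded input length.
#' @param convWidths kernel widths of the three 1D convolutions.
#' @param convFilters filter counts of the three convolutions.
#' @param gruHidden decoder GRU hidden width.
#' @param gruLayers decoder depth (3).
#' @param lrInit,lrFloor Adam learning rate and halting floor.
#' @param epochs epochs per fold; folds as in the GAE training loop.
#' @param folds cross-validation folds in the training loop.
#' @param batchSize sequences per gradient step.
#' @param bceWeight,klWeight loss weights (0.5 / 0.5).
#' @param seed RNG seed.
#' @return list of class `vaeConfig`.
#' @export
vaeConfig <- function(latentDim = 16L, maxLen = 140L,
                      convWidths = c(9L, 9L, 10L), convFilters = c(9L, 9L, 10L),
                      gruHidden = 501L, gruLayers = 3L,
                      lrInit = 1e-3, lrFloor = 1e-6, epochs = 10L, folds = 5L,
                      batchSize = 32L, bceWeight = 0.5, klWeight = 0.5,
                      seed = 1L) {
  stopifnot(latentDim %in% c(16L, 256L), length(convWidths) == 3L,
            length(convFilters) == 3L, lrFloor < lrInit)
  tOut <- maxLen - sum(convWidths - 1L)
  if (tOut < 1L) stop("maxLen too small for the convolution stack")
  structure(list(latentDim = latentDim, maxLen = maxLen,
                 convWidths = convWidths, convFilters = convFilters,
                 gruHidden = gruHidden, gruLayers = gruLayers,
                 lrInit = lrInit, lrFloor = lrFloor, epochs = epochs,
                 folds = folds, batchSize = batchSize,
                 bceWeight = bceWeight, klWeight = klWeight, seed = seed),
            class = "vaeConfig")
}

#' Initialize VAE parameters (Xavier uniform)
#'
#' @param config a [vaeConfig()].
#' @param vocabSize vocabulary size including the pad token.
#' @return named list of weight matrices and bias vectors.
#' @export
vaeInitParams <- function(config, vocabSize) {
  w <- config$convWidths; f <- config$convFilters
  cin <- c(vocabSize, f[1], f[2])
  tlen <- config$maxLen
  for (i in 1:3) tlen <- tlen - w[i] + 1L
  flat <- tlen * f[3]
  d <- config$latentDim; H <- config$gruHidden
  p <- list()
  for (i in 1:3) {
    p[[paste0("convW", i)]] <- xavierUniform(w[i] * cin[i], f[i])
    p[[paste0("convB", i)]] <- numeric(f[i])
  }
  p$Wmu <- xavierUniform(flat, d); p$bmu <- numeric(d)
  p$Wlv <- xavierUniform(flat, d); p$blv <- numeric(d)
  ins <- c(d, rep(H, config$gruLayers - 1L))
  for (l in seq_len(config$gruLayers)) {
    for (g in c("z", "r", "n")) {
      p[[paste0("W", g, l)]] <- xavierUniform(ins[l], H)
      p[[paste0("U", g, l)]] <- xavierUniform(H, H)
      p[[paste0("b", g, l)]] <- numeric(H)
    }
    p[[paste0("bh", l)]] <- numeric(H)
  }
  p$Wo <- xavierUniform(H, vocabSize); p$bo <- numeric(vocabSize)
  p
}

## one-hot list-of-timesteps from an index matrix
idxToOnehot <- function(idx, vocabSize) {
  B <- nrow(idx)
  lapply(seq_len(ncol(idx)), function(t) {
    M <- matrix(0, B, vocabSize)
    M[cbind(seq_len(B), idx[, t])] <- 1
    M
  })
}

convForward <- function(X, W, b, width) {
  tOut <- length(X) - width + 1L
  pre <- vector("list", tOut)
  for (t in seq_len(tOut)) {
    win <- do.call(cbind, X[t:(t + width - 1L)])
    pre[[t]] <- sweep(win %*% W, 2, b, `+`)
  }
  pre
}

## full forward + backward for one batch; returns loss pieces and gradients
vaeStep <- function(idx, params, config, computeGrads = TRUE, eps = NULL) {
  V <- ncol(params$Wo)
  B <- nrow(idx); Tm <- ncol(idx)
  w <- config$convWidths
  d <- config$latentDim; H <- config$gruHidden; nL <- config$gruLayers
  X <- idxToOnehot(idx, V)

  pre1 <- convForward(X, params$convW1, params$convB1, w[1])
  a1 <- lapply(pre1, selu)
  pre2 <- convForward(a1, params$convW2, params$convB2, w[2])
  a2 <- lapply(pre2, selu)
  pre3 <- convForward(a2, params$convW3, params$convB3, w[3])
  a3 <- lapply(pre3, selu)
  Fl <- do.call(cbind, a3)
  mu <- sweep(Fl %*% params$Wmu, 2, params$bmu, `+`)
  lv <- sweep(Fl %*% params$Wlv, 2, params$blv, `+`)
  lv <- pmin(pmax(lv, -15), 15)
  if (is.null(eps)) eps <- matrix(rnorm(B * d), B, d)
  z <- mu + exp(0.5 * lv) * eps

  hprev <- lapply(seq_len(nL), function(l) matrix(0, B, H))
  cache <- if (computeGrads) vector("list", Tm) else NULL
  bce <- 0
  Nrec <- B * Tm * V
  dOutList <- if (computeGrads) vector("list", Tm) else NULL
  epsP <- 1e-9
  for (t in seq_len(Tm)) {
    x <- z
    cc <- if (computeGrads) vector("list", nL) else NULL
    for (l in seq_len(nL)) {
      Wz <- params[[paste0("Wz", l)]]; Uz <- params[[paste0("Uz", l)]]
      Wr <- params[[paste0("Wr", l)]]; Ur <- params[[paste0("Ur", l)]]
      Wn <- params[[paste0("Wn", l)]]; Un <- params[[paste0("Un", l)]]
      h0 <- hprev[[l]]
      zg <- sigm(sweep(x %*% Wz + h0 %*% Uz, 2, params[[paste0("bz", l)]], `+`))
      rg <- sigm(sweep(x %*% Wr + h0 %*% Ur, 2, params[[paste0("br", l)]], `+`))
      q <- sweep(h0 %*% Un, 2, params[[paste0("bh", l)]], `+`)
      nn <- tanh(sweep(x %*% Wn, 2, params[[paste0("bn", l)]], `+`) + rg * q)
      h1 <- (1 - zg) * nn + zg * h0
      if (computeGrads) cc[[l]] <- list(x = x, h0 = h0, zg = zg, rg = rg,
                                        q = q, nn = nn)
      hprev[[l]] <- h1
      x <- h1
    }
    logits <- sweep(x %*% params$Wo, 2, params$bo, `+`)
    m <- apply(logits, 1, max)
    e <- exp(logits - m)
    p <- e / rowSums(e)
    tgt <- X[[t]]
    pc <- pmin(pmax(p, epsP), 1 - epsP)
    bce <- bce - sum(tgt * log(pc) + (1 - tgt) * log(1 - pc))
    if (computeGrads) {
      dp <- config$bceWeight * (pc - tgt) / (pc * (1 - pc)) / Nrec
      da <- p * (dp - rowSums(p * dp))
      dOutList[[t]] <- da
      cache[[t]] <- cc
    }
  }
  bce <- bce / Nrec
  kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / (B * d)
  loss <- config$bceWeight * bce + config$klWeight * kl
  if (!computeGrads)
    return(list(loss = loss, bce = bce, kl = kl, mu = mu, lv = lv, z = z))

  g <- lapply(params, function(p) p * 0)
  dhNext <- lapply(seq_len(nL), function(l) matrix(0, B, H))
  dz <- matrix(0, B, d)
  ## reconstruct h_t per layer for the output/backward pass: recompute
  ## hidden states sequence from caches (h1 = (1-zg)*nn + zg*h0)
  for (t in rev(seq_len(Tm))) {
    da <- dOutList[[t]]
    cc <- cache[[t]]
    h3 <- (1 - cc[[nL]]$zg) * cc[[nL]]$nn + cc[[nL]]$zg * cc[[nL]]$h0
    g$Wo <- g$Wo + t(h3) %*% da
    g$bo <- g$bo + colSums(da)
    dh <- da %*% t(params$Wo) + dhNext[[nL]]
    for (l in rev(seq_len(nL))) {
      cc_l <- cc[[l]]
      zg <- cc_l$zg; rg <- cc_l$rg; nn <- cc_l$nn; q <- cc_l$q
      h0 <- cc_l$h0; x <- cc_l$x
      dzg <- dh * (h0 - nn)
      dnn <- dh * (1 - zg)
      dh0 <- dh * zg
      dan <- dnn * (1 - nn^2)
      dq <- dan * rg
      drg <- dan * q
      daz <- dzg * zg * (1 - zg)
      dar <- drg * rg * (1 - rg)
      dx <- dan %*% t(params[[paste0("Wn", l)]]) +
            daz %*% t(params[[paste0("Wz", l)]]) +
            dar %*% t(params[[paste0("Wr", l)]])
      dh0 <- dh0 + dq %*% t(params[[paste0("Un", l)]]) +
             daz %*% t(params[[paste0("Uz", l)]]) +
             dar %*% t(params[[paste0("Ur", l)]])
      g[[paste0("Wn", l)]] <- g[[paste0("Wn", l)]] + t(x) %*% dan
      g[[paste0("Wz", l)]] <- g[[paste0("Wz", l)]] + t(x) %*% daz
      g[[paste0("Wr", l)]] <- g[[paste0("Wr", l)]] + t(x) %*% dar
      g[[paste0("Un", l)]] <- g[[paste0("Un", l)]] + t(h0) %*% dq
      g[[paste0("Uz", l)]] <- g[[paste0("Uz", l)]] + t(h0) %*% daz
      g[[paste0("Ur", l)]] <- g[[paste0("Ur", l)]] + t(h0) %*% dar
      g[[paste0("bn", l)]] <- g[[paste0("bn", l)]] + colSums(dan)
      g[[paste0("bz", l)]] <- g[[paste0("bz", l)]] + colSums(daz)
      g[[paste0("br", l)]] <- g[[paste0("br", l)]] + colSums(dar)
      g[[paste0("bh", l)]] <- g[[paste0("bh", l)]] + colSums(dq)
      dhNext[[l]] <- dh0
      if (l > 1L) dh <- dx + dhNext[[l - 1L]]
      else dz <- dz + dx
    }
  }
  ## latent heads (+ KL gradients)
  dmu <- dz + config$klWeight * mu / (B * d)
  dlv <- dz * eps * 0.5 * exp(0.5 * lv) +
         config$klWeight * 0.5 * (exp(lv) - 1) / (B * d)
  g$Wmu <- t(Fl) %*% dmu; g$bmu <- colSums(dmu)
  g$Wlv <- t(Fl) %*% dlv; g$blv <- colSums(dlv)
  dFl <- dmu %*% t(params$Wmu) + dlv %*% t(params$Wlv)
  ## un-flatten to per-timestep grads for conv layer 3 activations
  f3 <- config$convFilters[3]
  t3 <- length(pre3)
  dA3 <- lapply(seq_len(t3), function(t) dFl[, ((t - 1) * f3 + 1):(t * f3), drop = FALSE])
  convBack <- function(dAct, pre, Xin, W, width, wName, bName) {
    tOut <- length(pre)
    dIn <- lapply(Xin, function(M) M * 0)
    for (t in seq_len(tOut)) {
      dPre <- dAct[[t]] * seluGrad(pre[[t]])
      win <- do.call(cbind, Xin[t:(t + width - 1L)])
      g[[wName]] <<- g[[wName]] + t(win) %*% dPre
      g[[bName]] <<- g[[bName]] + colSums(dPre)
      dWin <- dPre %*% t(W)
      cin <- ncol(Xin[[1]])
      for (k in seq_len(width)) {
        cols <- ((k - 1) * cin + 1):(k * cin)
        dIn[[t + k - 1L]] <- dIn[[t + k - 1L]] + dWin[, cols, drop = FALSE]
      }
    }
    dIn
  }
  dA2 <- convBack(dA3, pre3, a2, params$convW3, w[3], "convW3", "convB3")
  dA1 <- convBack(dA2, pre2, a1, params$convW2, w[2], "convW2", "convB2")
  invisible(convBack(dA1, pre1, X, params$convW1, w[1], "convW1", "convB1"))
  list(loss = loss, bce = bce, kl = kl, grads = g)
}

#' Train the SMILES variational autoencoder
#'
#' Same training protocol as [trainGAE()]: the corpus is shuffled into
#' `folds` folds, the model is trained for `epochs` epochs on each fold's
#' training portion with Adam, the learning rate halves when an epoch fails
#' to improve the loss (patience 1), and training halts at the learning-rate
#' floor. Reproducible under the config seed. Aborts on a non-finite loss.
#'
#' @param corpus character vector of accepted (standardized, length-filtered)
#'   SMILES.
#' @param config a [vaeConfig()].
#' @return list with `params`, `vocab`, `log` (fold, epoch, lr, loss, bce,
#'   kl) and `config`.
#' @export
trainVAE <- function(corpus, config = vaeConfig()) {
  stopifnot(length(corpus) >= 2L)
  set.seed(config$seed)
  vocab <- vaeVocab(corpus)
  params <- vaeInitParams(config, length(vocab))
  idxAll <- smilesToIdx(corpus, vocab, config$maxLen)
  n <- length(corpus)
  foldId <- sample(rep_len(seq_len(config$folds), n))
  opt <- adamInit(params)
  lr <- config$lrInit
  log <- list(); best <- Inf; halted <- FALSE
  for (f in seq_len(config$folds)) {
    trainIdx <- if (config$folds > 1L) which(foldId != f) else seq_len(n)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(trainIdx)
      el <- 0; eb <- 0; ek <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = config$batchSize)) {
        rows <- ord[start:min(start + config$batchSize - 1L, length(ord))]
        st <- vaeStep(idxAll[rows, , drop = FALSE], params, config)
        if (!is.finite(st$loss))
          stop("VAE training diverged (non-finite loss) at fold ", f,
               " epoch ", ep)
        upd <- adamStep(params, st$grads, opt, lr)
        params <- upd$params; opt <- upd$state
        el <- el + st$loss; eb <- eb + st$bce; ek <- ek + st$kl; nb <- nb + 1L
      }
      log[[length(log) + 1L]] <- data.frame(fold = f, epoch = ep, lr = lr,
                                            loss = el / nb, bce = eb / nb,
                                            kl = ek / nb)
      if (el / nb >= best) lr <- lr / 2 else best <- el / nb
      if (lr <= config$lrFloor || el / nb == 0) { halted <- TRUE; break }
    }
    if (halted) break
  }
  list(params = params, vocab = vocab, log = do.call(rbind, log),
       config = config)
}

#' VAE latent fingerprint of a molecule
#'
#' Deterministic fingerprint: the posterior mean vector of the encoder (no
#' latent sampling). Characters unseen during training map to the pad slot
#' with a warning.
#'
#' @param smiles a SMILES string (length <= the model's `maxLen`).
#' @param model result of [trainVAE()].
#' @return numeric vector of length `latentDim`.
#' @export
vaeFingerprint <- function(smiles, model) {
  idx <- smilesToIdx(smiles, model$vocab, model$config$maxLen)
  B <- nrow(idx); d <- model$config$latentDim
  st <- vaeStep(idx, model$params, model$config, computeGrads = FALSE,
                eps = matrix(0, B, d))
  st$mu[1L, ]
}

#' VAE fingerprints for a set of molecules
#'
#' @param smiles character vector of SMILES.
#' @param ids compound ids.
#' @param model result of [trainVAE()].
#' @return a [FingerprintMatrix-class] (continuous, sequence subtype).
#' @export
vaeFingerprintMatrix <- function(smiles, ids, model) {
  stopifnot(length(smiles) == length(ids))
  idx <- smilesToIdx(smiles, model$vocab, model$config$maxLen)
  st <- vaeStep(idx, model$params, model$config, computeGrads = FALSE,
                eps = matrix(0, nrow(idx), model$config$latentDim))
  vals <- st$mu
  rownames(vals) <- ids
  FingerprintMatrix(vals, "continuous", "data", "sequence")
}
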