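# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

fxAccepted <- function() {
  if (is.null(.fx$accepted)) {
    mols <- genMolecules(60, seed = 101L)
    rec <- standardizeMolecules(mols$smiles, mols$id)
    acc <- filterByLength(rec)
    keep <- mols[match(acc$id, mols$id), , drop = FALSE]
    keep$smiles_std <- acc$smiles_std
    rownames(keep) <- NULL
    .fx$accepted <- keep
  }
  .fx$accepted
}

fxGraphs <- function(n = 20L) {
  if (is.null(.fx$graphs)) {
    keep <- fxAccepted()
    .fx$graphs <- molecularGraphs(stats::setNames(keep$smiles_std, keep$id))
  }
  .fx$graphs[seq_len(n)]
}

fxRuleFps <- function() {
  if (is.null(.fx$ruleFps)) {
    keep <- fxAccepted()
    .fx$ruleFps <- list(
      morgan300 = ruleFingerprintMatrix(keep$smiles_std, keep$id, "morgan300"),
      topo1024 = ruleFingerprintMatrix(keep$smiles_std, keep$id, "topo1024"))
  }
  .fx$ruleFps
}

# independent brute-force silhouette for 1D points (plain double loop)
bruteSilhouette <- function(x, labels) {
  labels <- as.character(labels)
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(abs(x[i] - x[same]))
    b <- Inf
    for (k in unique(labels[labels != labels[i]]))
      b <- min(b, mean(abs(x[i] - x[labels == k])))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# random small molecular-style graph (connected path plus random extra edges)
randomGraph <- function(V, seed) {
  set.seed(seed)
  A <- matrix(0, V, V)
  if (V > 1) for (k in seq_len(V - 1)) { A[k, k + 1] <- 1; A[k + 1, k] <- 1 }
  extra <- which(upper.tri(A) & A == 0)
  if (length(extra) && V > 2) {
    add <- sample(extra, min(length(extra), max(0, rpois(1, 2))))
    A[add] <- 1
    A <- pmax(A, t(A))
  }
  A
}
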