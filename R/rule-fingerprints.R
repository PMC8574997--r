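## Rule-based binary fingerprints via OpenBabel: extended-connectivity
## (circular, "Morgan") bits folded to 300/1024, and the 1024-bit
## path-based (topological, FP2) fingerprint.

obFingerprint <- function(smiles, name) {
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  ChemmineOB::fingerprint_OB(mol, name)
}

foldBits <- function(bits, nBits) {
  idx <- which(bits != 0) - 1L
  out <- numeric(nBits)
  out[unique(idx %% nBits) + 1L] <- 1
  out
}

#' Folded circular (Morgan-type) fingerprint
#'
#' Extended-connectivity fingerprint of atom-centered circular neighborhoods
#' (default radius 2, the ECFP4-equivalent community default), folded by
#' modular hashing to the requested width. Deterministic for a fixed
#' OpenBabel version and invariant to SMILES atom ordering (the circular
#' construction depends only on the molecular graph).
#'
#' @param smiles a standardized SMILES string.
#' @param nBits fingerprint width, 300 or 1024.
#' @param radius circular neighborhood radius (default 2).
#' @return binary numeric vector of length `nBits`.
#' @export
morganFingerprint <- function(smiles, nBits = 1024L, radius = 2L) {
  if (!nBits %in% c(300L, 1024L))
    stop("config error: morgan nBits must be 300 or 1024, got ", nBits)
  if (!radius %in% 0:5)
    stop("config error: morgan radius must be in 0..5")
  foldBits(obFingerprint(smiles, paste0("ECFP", 2L * radius)), nBits)
}

#' Path-based (topological) fingerprint
#'
#' 1024-bit hashed encoding of linear bond paths of up to seven atoms
#' (OpenBabel FP2). Deterministic and atom-order invariant.
#'
#' @param smiles a standardized SMILES string.
#' @param nBits fingerprint width; the path fingerprint is defined at 1024.
#' @return binary numeric vector of length 1024.
#' @export
topologicalFingerprint <- function(smiles, nBits = 1024L) {
  if (nBits != 1024L)
    stop("config error: topological fingerprint is defined at 1024 bits")
  as.numeric(obFingerprint(smiles, "FP2") != 0)
}

#' Adapter slot for 3D circular fingerprints
#'
#' Placeholder for a conformer-based 3D extended-connectivity backend.
#' No such backend ships with the package, so calling this raises a
#' capability error; the slot exists so that a 3D fingerprint provider can
#' be plugged into the same benchmarking surface.
#'
#' @param smiles a standardized SMILES string.
#' @param nBits fingerprint width (1024).
#' @param backend optional function(smiles, nBits) supplied by the user.
#' @return binary numeric vector of length `nBits` when a backend is given.
#' @export
e3fpAdapter <- function(smiles, nBits = 1024L, backend = NULL) {
  if (is.null(backend)) {
    cond <- structure(
      class = c("fpbench_capability_error", "error", "condition"),
      list(message = paste("3D circular fingerprint backend not available;",
                           "supply `backend` to use this adapter"),
           call = sys.call()))
    stop(cond)
  }
  fp <- backend(smiles, nBits)
  stopifnot(length(fp) == nBits, all(fp %in% c(0, 1)))
  fp
}

#' Generate a FingerprintMatrix for a set of molecules
#'
#' Convenience builder mapping a fingerprint tag to its generator and
#' stacking per-molecule vectors into a [FingerprintMatrix-class].
#' Supported rule-based tags: `"morgan300"`, `"morgan1024"`, `"topo1024"`.
#'
#' @param smiles character vector of standardized SMILES.
#' @param ids compound identifiers (row names).
#' @param type fingerprint tag.
#' @param radius circular radius for the morgan variants.
#' @return a [FingerprintMatrix-class] object.
#' @export
ruleFingerprintMatrix <- function(smiles, ids, type = c("morgan300", "morgan1024", "topo1024"),
                                  radius = 2L) {
  type <- match.arg(type)
  stopifnot(length(smiles) == length(ids))
  gen <- switch(type,
    morgan300 = function(s) morganFingerprint(s, 300L, radius),
    morgan1024 = function(s) morganFingerprint(s, 1024L, radius),
    topo1024 = function(s) topologicalFingerprint(s, 1024L))
  vals <- t(vapply(smiles, gen, numeric(if (type == "morgan300") 300L else 1024L)))
  rownames(vals) <- ids
  FingerprintMatrix(vals, "binary", "rule",
                    if (type == "topo1024") "path" else "circular-2D")
}
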