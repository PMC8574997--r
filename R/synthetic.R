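## Synthetic inputs with known ground truth: a fragment-grammar molecule
## generator, combination screens with a planted structure+cell-line signal,
## and structure-correlated class labels.

## chainable scaffold units defining the 12 planted families
FAMILY_UNITS <- c(
  benzene      = "c1ccccc1",
  pyridine     = "c1ccncc1",
  thiophene    = "c1ccsc1",
  furan        = "c1ccoc1",
  pyrrole      = "c1cc[nH]c1",
  cyclohexane  = "C1CCCCC1",
  cyclopentane = "C1CCCC1",
  cyclopropane = "C1CC1",
  piperidine   = "C1CCNCC1",
  oxane        = "C1CCOCC1",
  naphthalene  = "c1ccc2ccccc2c1",
  anilide      = "C(=O)Nc1ccccc1"
)

CHAIN_UNITS <- c("C", "CC", "CCC", "CO", "CN", "C(C)", "C(F)(F)", "S", "O",
                 "N(C)", "C(=O)", "C(=O)O", "C(=O)N", "C=C")
CHIRAL_UNITS <- c("[C@H](C)", "[C@@H](O)", "[C@H](N)", "[C@@H](F)")
CHARGED_UNITS <- c("[N+](C)(C)")
TERMINAL_UNITS <- c("C", "O", "N", "F", "Cl", "Br", "I", "C(=O)O", "C#N",
                    "C(F)(F)F", "OC", "N(C)C", "C(=O)[O-]")
START_UNITS <- c("C", "CC", "N", "OC")

#' Generate synthetic drug-like SMILES
#'
#' Assembles valid SMILES from a curated fragment grammar: a start unit, a
#' run of chainable units (alkyl, heteroatom, carbonyl, chiral and charged
#' fragments), one scaffold unit drawn from 12 ring families (recorded as
#' the molecule's `family`), and a terminal unit. A small fraction of
#' molecules is deliberately emitted below 8 or above 140 characters so the
#' standardization length filter is exercised. Pure function of
#' `(n, seed)`.
#'
#' @param n number of molecules (>= 1).
#' @param seed RNG seed.
#' @return data.frame with columns `id`, `smiles`, `family`.
#' @export
genMolecules <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  fams <- names(FAMILY_UNITS)
  ids <- sprintf("syn%04d", seq_len(n))
  smiles <- character(n); family <- character(n)
  for (i in seq_len(n)) {
    u <- runif(1)
    fam <- fams[((i - 1L) %% length(fams)) + 1L]
    if (u < 0.02) {
      smiles[i] <- sample(c("CCO", "CC=O", "OCC"), 1L)  # below the filter
      family[i] <- "tiny"
      next
    }
    if (u < 0.04) {
      smiles[i] <- paste0(paste(rep("CC(C)C(=O)OC", 13L), collapse = ""), "C")
      family[i] <- "oversize"                            # above the filter
      next
    }
    nUnits <- sample(2:7, 1L)
    pool <- c(sample(CHAIN_UNITS, nUnits, replace = TRUE),
              if (runif(1) < 0.45) sample(CHIRAL_UNITS, 1L),
              if (runif(1) < 0.15) CHARGED_UNITS)
    pool <- sample(pool)   # shuffle chain
    at <- sample(seq_len(length(pool) + 1L), 1L)
    body <- append(pool, FAMILY_UNITS[[fam]], after = at - 1L)
    smiles[i] <- paste0(sample(START_UNITS, 1L), paste(body, collapse = ""),
                        sample(TERMINAL_UNITS, 1L))
    family[i] <- fam
  }
  data.frame(id = ids, smiles = smiles, family = family,
             stringsAsFactors = FALSE)
}

## simple interpretable molecule descriptors from the SMILES annotations
moleculeDescriptors <- function(smiles) {
  t(vapply(smiles, function(s) {
    at <- smilesAtoms(s)
    c(heavy = nrow(at),
      aromatic = sum(at$aromatic),
      hetero = sum(at$symbol %in% c("N", "O", "S")),
      halogen = sum(at$symbol %in% c("F", "Cl", "Br", "I")),
      charged = sum(at$charge != 0),
      chiral = sum(at$chirality != "unspecified"))
  }, numeric(6)))
}

#' Specification of a synthetic combination screen
#'
#' @param nCellLines number of cell lines.
#' @param nTuples number of unique (pair, cell line) tuples.
#' @param replicateRate fraction of tuples receiving a second biological
#'   replicate.
#' @param signalFraction rho, the fraction of each score's variance
#'   explained by structure + cell line (planted exactly by construction).
#' @param noiseSd alternative noise parameterization; supply either
#'   `signalFraction` or `noiseSd`, not both.
#' @param interScoreCor fraction of the noise shared between the five
#'   scores (drives inter-score correlation beyond the shared signal).
#' @param replicateSd replicate noise, as a fraction of each score's scale.
#' @param seed RNG seed.
#' @return list of class `screenSpec`.
#' @export
screenSpec <- function(nCellLines = 5L, nTuples = 1000L, replicateRate = 0.2,
                       signalFraction = 0.5, noiseSd = NULL,
                       interScoreCor = 0.3, replicateSd = 0.1, seed = 1L) {
  if (!is.null(noiseSd) && !missing(signalFraction))
    stop("config error: supply either signalFraction or noiseSd, not both")
  if (!is.null(noiseSd)) signalFraction <- 1 / (1 + noiseSd^2)
  stopifnot(signalFraction >= 0, signalFraction <= 1,
            replicateRate >= 0, replicateRate <= 1,
            interScoreCor >= 0, interScoreCor <= 1)
  structure(list(nCellLines = nCellLines, nTuples = nTuples,
                 replicateRate = replicateRate,
                 signalFraction = signalFraction,
                 interScoreCor = interScoreCor, replicateSd = replicateSd,
                 seed = seed),
            class = "screenSpec")
}

SCORE_AFFINE <- list(css = c(50, 15), bliss = c(5, 6), hsa = c(3, 5),
                     loewe = c(2, 7), zip = c(4, 6))

#' Generate a synthetic combination screen with a planted signal
#'
#' Each tuple's latent response is a linear function of interpretable pair
#' descriptors (heavy-atom, aromatic, heteroatom, halogen, charge and
#' chirality counts of the two drugs) plus a cell-line effect,
#' standardized, and mixed with Gaussian noise so that the fraction of each
#' score's variance explained by structure + cell line equals
#' `signalFraction` exactly in the generative model. The five scores are
#' correlated affine transforms of this latent (sharing `interScoreCor` of
#' their noise). Tuples receive a biological replicate at `replicateRate`.
#'
#' @param molecules data.frame from [genMolecules()] (or any `id`, `smiles`
#'   table).
#' @param spec a [screenSpec()].
#' @return list with `tuples` (data.frame: drug_a, drug_b, cell_line,
#'   replicate, css, bliss, hsa, loewe, zip) and `truth` (beta, cell
#'   effects, rho, per-tuple ideal design matrix, PCC ceiling sqrt(rho)).
#' @export
genScreen <- function(molecules, spec = screenSpec()) {
  stopifnot(nrow(molecules) >= 2L, spec$nCellLines >= 1L)
  set.seed(spec$seed)
  rho <- spec$signalFraction
  desc <- moleculeDescriptors(molecules$smiles)
  rownames(desc) <- molecules$id
  nPairs <- choose(nrow(molecules), 2L)
  maxTuples <- nPairs * spec$nCellLines
  if (spec$nTuples > maxTuples)
    stop("config error: nTuples exceeds available pair x cell combinations")
  pick <- sample(maxTuples, spec$nTuples)
  pairIdx <- (pick - 1L) %% nPairs + 1L
  cellIdx <- (pick - 1L) %/% nPairs + 1L
  pairs <- t(utils::combn(nrow(molecules), 2L))[pairIdx, , drop = FALSE]
  cells <- paste0("cell", cellIdx)
  ia <- pairs[, 1L]; ib <- pairs[, 2L]
  Dp <- cbind(desc[ia, , drop = FALSE] + desc[ib, , drop = FALSE],
              abs(desc[ia, , drop = FALSE] - desc[ib, , drop = FALSE]))
  colnames(Dp) <- c(paste0(colnames(desc), "_sum"),
                    paste0(colnames(desc), "_diff"))
  beta <- rnorm(ncol(Dp))
  cellEffects <- rnorm(spec$nCellLines)
  structPart <- as.numeric(Dp %*% beta)
  signal <- structPart + cellEffects[cellIdx] * stats::sd(structPart)
  sdSig <- sqrt(mean((signal - mean(signal))^2))
  sig0 <- if (sdSig > 0) (signal - mean(signal)) / sdSig else signal * 0
  n <- spec$nTuples
  shared <- rnorm(n)
  w <- spec$interScoreCor
  scores <- sapply(names(SCORE_AFFINE), function(s) {
    own <- rnorm(n)
    noise <- sqrt(w) * shared + sqrt(1 - w) * own
    af <- SCORE_AFFINE[[s]]
    af[1] + af[2] * (sqrt(rho) * sig0 + sqrt(1 - rho) * noise)
  })
  tuples <- data.frame(drug_a = molecules$id[ia], drug_b = molecules$id[ib],
                       cell_line = cells, replicate = 1L,
                       scores, stringsAsFactors = FALSE)
  names(tuples)[5:9] <- names(SCORE_AFFINE)
  repIdx <- which(runif(n) < spec$replicateRate)
  if (length(repIdx)) {
    reps <- tuples[repIdx, , drop = FALSE]
    reps$replicate <- 2L
    for (s in names(SCORE_AFFINE))
      reps[[s]] <- reps[[s]] +
        rnorm(length(repIdx), sd = spec$replicateSd * SCORE_AFFINE[[s]][2])
    tuples <- rbind(tuples, reps)
  }
  rownames(tuples) <- NULL
  cellOnehot <- outer(cellIdx, seq_len(spec$nCellLines), `==`) * 1
  colnames(cellOnehot) <- paste0("cell", seq_len(spec$nCellLines))
  list(tuples = tuples,
       truth = list(beta = beta, cellEffects = cellEffects, rho = rho,
                    pccCeiling = sqrt(rho),
                    idealDesign = cbind(Dp, cellOnehot),
                    latentSignal = sig0,
                    tupleKey = data.frame(drug_a = molecules$id[ia],
                                          drug_b = molecules$id[ib],
                                          cell_line = cells,
                                          stringsAsFactors = FALSE)))
}

#' Assign structure-correlated class labels
#'
#' Classes follow the planted scaffold families from [genMolecules()]
#' (families merged round-robin into K classes), so structure-aware
#' fingerprints separate the classes. Without a `family` column, molecules
#' are grouped by hierarchical clustering of simple structural descriptors.
#' Classes are rebalanced deterministically so each has >= 2 members.
#'
#' @param molecules data.frame with `id`, `smiles` and optionally `family`.
#' @param K number of classes (default 10; K <= n required).
#' @param seed RNG seed (used only for descriptor-based fallback ties).
#' @return data.frame with columns `drug_id`, `class`.
#' @export
genClassLabels <- function(molecules, K = 10L, seed = 1L) {
  n <- nrow(molecules)
  if (K > n) stop("K exceeds the number of molecules")
  if (!is.null(molecules$family)) {
    fams <- sort(unique(molecules$family))
    map <- setNames(((seq_along(fams) - 1L) %% K) + 1L, fams)
    cls <- map[molecules$family]
  } else {
    set.seed(seed)
    D <- moleculeDescriptors(molecules$smiles)
    hc <- hclust(dist(D), method = "ward.D2")
    cls <- cutree(hc, k = K)
  }
  cls <- as.integer(cls)
  ## deterministic rebalancing: every class needs >= 2 members
  repeat {
    tab <- tabulate(cls, K)
    small <- which(tab < 2L)
    if (!length(small)) break
    donor <- which.max(tab)
    mover <- which(cls == donor)[1L]
    cls[mover] <- small[1L]
  }
  data.frame(drug_id = molecules$id, class = paste0("class", cls),
             stringsAsFactors = FALSE)
}
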