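## Molecule standardization and graph featurization.
##
## OpenBabel (through ChemmineOB/ChemmineR) is the SMILES parser and
## canonicalizer. Per-atom annotations that OpenBabel's SDF export does not
## carry (formal charge, tetrahedral chirality, aromaticity) are read off the
## canonical SMILES string itself with a small lexer; the SDF atom order
## matches the canonical-SMILES atom order, so annotations align with the
## bond-derived adjacency.

obCanonical <- function(smiles) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))
  out <- sub("[\t ].*$", "", trimws(out))
  if (!nzchar(out))
    stop("SMILES parse error: '", smiles, "'", call. = FALSE)
  out
}

#' Tokenize per-atom annotations from a SMILES string
#'
#' Enumerates the atoms of a (canonical) SMILES string in order of
#' appearance and reports the element symbol, aromaticity (lowercase
#' notation), formal charge and tetrahedral chirality tag of each. This is
#' an annotation reader, not a structure parser: bonds and connectivity
#' always come from OpenBabel.
#'
#' @param smiles a single SMILES string.
#' @return data.frame with columns `symbol`, `aromatic`, `charge`,
#'   `chirality` (one of `"unspecified"`, `"CW"`, `"CCW"`, `"other"`).
#' @export
smilesAtoms <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  sym <- aro <- chg <- chi <- list()
  i <- 1L
  push <- function(symbol, aromatic, charge, chirality) {
    sym[[length(sym) + 1L]] <<- symbol
    aro[[length(aro) + 1L]] <<- aromatic
    chg[[length(chg) + 1L]] <<- charge
    chi[[length(chi) + 1L]] <<- chirality
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket in SMILES: '", smiles, "'")
      content <- substr(smiles, i + 1L, j - 1L)
      m <- regexec(
        "^([0-9]*)([A-Z][a-z]?|[a-z][a-z]?)(@[A-Z]{2}[0-9]+|@@|@)?(H[0-9]*)?([+-][0-9]*|\\++|-+)?$",
        content)
      parts <- regmatches(content, m)[[1]]
      if (!length(parts))
        stop("cannot read bracket atom '[", content, "]' in '", smiles, "'")
      symbol <- parts[3]
      chirality <- switch(parts[4],
                          "@@" = "CW", "@" = "CCW",
                          if (nzchar(parts[4])) "other" else "unspecified")
      charge <- 0L
      cstr <- parts[6]
      if (nzchar(cstr)) {
        if (grepl("^[+-][0-9]+$", cstr)) {
          charge <- as.integer(substring(cstr, 2))
          if (substr(cstr, 1, 1) == "-") charge <- -charge
        } else {
          charge <- nchar(cstr) * if (substr(cstr, 1, 1) == "+") 1L else -1L
        }
      }
      aromatic <- symbol == tolower(symbol)
      if (aromatic) substr(symbol, 1, 1) <- toupper(substr(symbol, 1, 1))
      push(symbol, aromatic, charge, chirality)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push(paste0(ch, chars[i + 1L]), FALSE, 0L, "unspecified")
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "S", "P", "F", "I")) {
      push(ch, FALSE, 0L, "unspecified")
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "s", "p")) {
      push(toupper(ch), TRUE, 0L, "unspecified")
      i <- i + 1L
    } else if (ch == "%") {
      i <- i + 3L
    } else if (ch %in% c("(", ")", "-", "=", "#", "$", ":", "/", "\\", ".",
                         "~", "+") || grepl("[0-9]", ch)) {
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES '", smiles, "'")
    }
  }
  data.frame(symbol = unlist(sym), aromatic = unlist(aro),
             charge = unlist(chg), chirality = unlist(chi),
             stringsAsFactors = FALSE)
}

#' Standardize SMILES strings
#'
#' Canonicalizes each SMILES with OpenBabel and strips salt/solvent
#' components by keeping the largest fragment by heavy-atom count (ties
#' broken by the lexicographically smallest canonical SMILES). Unparseable
#' input raises an error naming the offending string.
#'
#' @param smiles character vector of raw SMILES.
#' @return character vector of standardized canonical SMILES.
#' @examples
#' standardizeSmiles("CCO.[Na+]")  # "CCO"
#' @export
standardizeSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    can <- obCanonical(s)
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(can)
    frags <- vapply(frags, obCanonical, character(1))
    heavy <- vapply(frags, function(f) {
      at <- smilesAtoms(f)
      sum(at$symbol != "H")
    }, numeric(1))
    cand <- frags[heavy == max(heavy)]
    sort(cand)[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Build a molecule record table from raw SMILES
#'
#' Tolerant, tabular counterpart of [standardizeSmiles()]: parse failures
#' are recorded as rejected rows instead of raised.
#'
#' @param smiles character vector of raw SMILES.
#' @param ids compound identifiers (defaults to `mol1..molN`).
#' @return data.frame with columns `id`, `smiles_raw`, `smiles_std`,
#'   `accepted`, `reason`.
#' @export
standardizeMolecules <- function(smiles, ids = NULL) {
  if (is.null(ids))
    ids <- if (length(smiles)) paste0("mol", seq_along(smiles)) else character(0)
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  std <- character(length(smiles)); ok <- logical(length(smiles))
  reason <- character(length(smiles))
  for (i in seq_along(smiles)) {
    res <- tryCatch(standardizeSmiles(smiles[i]), error = function(e) e)
    if (inherits(res, "error")) {
      std[i] <- NA_character_; ok[i] <- FALSE; reason[i] <- "parse error"
    } else {
      std[i] <- res; ok[i] <- TRUE; reason[i] <- ""
    }
  }
  data.frame(id = ids, smiles_raw = smiles, smiles_std = std,
             accepted = ok, reason = reason, stringsAsFactors = FALSE)
}

#' Filter molecule records by standardized-SMILES length
#'
#' Keeps records whose standardized SMILES length lies in
#' `[minLen, maxLen]` (default 8..140 characters). The filter is applied
#' to the standardized string. Rejected rows (including earlier parse
#' failures) are returned in the `"rejected"` attribute with reasons.
#'
#' @param records data.frame from [standardizeMolecules()].
#' @param minLen,maxLen inclusive length bounds.
#' @return the accepted subset of `records`; rejected rows as
#'   `attr(, "rejected")`.
#' @export
filterByLength <- function(records, minLen = 8L, maxLen = 140L) {
  stopifnot(is.data.frame(records), "smiles_std" %in% names(records))
  len <- nchar(records$smiles_std)
  reason <- records$reason
  ok <- records$accepted
  tooShort <- ok & len < minLen
  tooLong <- ok & len > maxLen
  reason[tooShort] <- sprintf("too short (%d < %d)", len[tooShort], minLen)
  reason[tooLong] <- sprintf("too long (%d > %d)", len[tooLong], maxLen)
  ok <- ok & !tooShort & !tooLong
  records$accepted <- ok
  records$reason <- reason
  kept <- records[ok, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "rejected") <- records[!ok, , drop = FALSE]
  kept
}

#' Read a .smi file (one molecule per line, "SMILES<tab>id")
#'
#' @param path file path; lines with no id get `mol<line>` ids.
#' @return data.frame with columns `id`, `smiles`.
#' @export
readSmiFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else paste0("mol", i)
  }, character(1))
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

## Parse one standardized SMILES into atoms + adjacency via OpenBabel SDF.
parseMolecule <- function(smilesStd) {
  atomsOnly <- smilesAtoms(smilesStd)
  if (nrow(atomsOnly) == 1L)  # single atom: no bonds to read
    return(list(smiles = smilesStd, atoms = atomsOnly,
                adjacency = matrix(0, 1, 1)))
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smilesStd, "m"))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  nAtoms <- nrow(ab)
  atoms <- smilesAtoms(smilesStd)
  if (nrow(atoms) != nAtoms)
    stop("atom count mismatch between SMILES annotations (", nrow(atoms),
         ") and parsed structure (", nAtoms, ") for '", smilesStd, "'")
  A <- matrix(0, nAtoms, nAtoms)
  bb <- ChemmineR::bondblock(sdf)
  if (nrow(bb) > 0) {
    for (b in seq_len(nrow(bb))) {
      i <- bb[b, 1]; j <- bb[b, 2]
      A[i, j] <- 1; A[j, i] <- 1
    }
  }
  list(smiles = smilesStd, atoms = atoms, adjacency = A)
}

#' Default 37-element atom-type list for node featurization
#'
#' The common organic/druglike elements routed to named one-hot slots;
#' anything else falls into the 38th ("unknown") slot. Membership only
#' affects one-hot routing, never dimensions.
#'
#' @return character vector of 37 element symbols.
#' @export
defaultAtomTypes <- function() {
  c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
    "Si", "Se", "As", "Na", "K", "Li", "Mg", "Ca", "Zn", "Fe",
    "Cu", "Mn", "Co", "Ni", "Cr", "Mo", "V", "Al", "Sn", "Sb",
    "Bi", "Ag", "Au", "Pt", "Pd", "Hg", "Ti")
}

#' One-hot atom featurization (54 features per atom)
#'
#' Encodes each atom as the concatenation of one-hot blocks: 38 atom types
#' (37 named + unknown), 6 degree bins (0..5), 5 formal-charge bins
#' (-2..+2), 4 chirality variants (unspecified, CW, CCW, other) and a
#' single aromaticity flag. Every row therefore sums to 4 (plus 1 for
#' aromatic atoms). Degrees or charges outside the bins are clamped to the
#' nearest bin with a warning.
#'
#' @param mol a standardized SMILES string or the result of the internal
#'   parser (list with `atoms` and `adjacency`).
#' @param atomTypes character vector of 37 named element slots.
#' @return numeric |V| x 54 matrix.
#' @export
featurizeAtoms <- function(mol, atomTypes = defaultAtomTypes()) {
  if (is.character(mol)) mol <- parseMolecule(mol)
  stopifnot(length(atomTypes) == 37L)
  atoms <- mol$atoms
  nV <- nrow(atoms)
  degree <- rowSums(mol$adjacency)
  X <- matrix(0, nV, 54L)
  for (i in seq_len(nV)) {
    slot <- match(atoms$symbol[i], atomTypes)
    if (is.na(slot)) slot <- 38L
    X[i, slot] <- 1
    d <- degree[i]
    if (d > 5) { warning("degree ", d, " clamped to bin 5"); d <- 5 }
    X[i, 39L + d] <- 1
    q <- atoms$charge[i]
    if (q < -2 || q > 2) {
      warning("formal charge ", q, " clamped to nearest bin")
      q <- max(-2L, min(2L, q))
    }
    X[i, 44L + (q + 3L)] <- 1
    ci <- match(atoms$chirality[i], c("unspecified", "CW", "CCW", "other"))
    X[i, 49L + ci] <- 1
    if (atoms$aromatic[i]) X[i, 54L] <- 1
  }
  X
}

#' Binary adjacency matrix of a molecule
#'
#' Bond presence only (bond order ignored); symmetric with zero diagonal.
#'
#' @param mol standardized SMILES string or parsed molecule.
#' @return binary |V| x |V| matrix.
#' @export
buildAdjacency <- function(mol) {
  if (is.character(mol)) mol <- parseMolecule(mol)
  mol$adjacency
}

#' Symmetric self-loop degree normalization of an adjacency matrix
#'
#' Computes `D^-1/2 (A + I) D^-1/2`, where `D` is the diagonal degree
#' matrix of `A + I`. Isolated atoms get degree 1 from their self-loop, so
#' the map is defined for every graph with at least one node.
#'
#' @param A binary symmetric adjacency, zero diagonal.
#' @return normalized adjacency, symmetric with entries in (0, 1] wherever
#'   `A + I` is non-zero.
#' @export
normalizeAdjacency <- function(A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  if (nrow(A)) stopifnot(all(A == t(A)), all(diag(A) == 0))
  Asl <- A + diag(nrow(A))
  dInv <- 1 / sqrt(rowSums(Asl))
  outer(dInv, dInv) * Asl
}

#' Build a MolecularGraph from a standardized SMILES
#'
#' @param smilesStd standardized SMILES string.
#' @param atomTypes atom-type slots, see [featurizeAtoms()].
#' @return a [MolecularGraph-class] object.
#' @export
molecularGraph <- function(smilesStd, atomTypes = defaultAtomTypes()) {
  mol <- parseMolecule(smilesStd)
  A <- mol$adjacency
  new("MolecularGraph", smiles = smilesStd, adjacency = A,
      adjNorm = normalizeAdjacency(A),
      nodeFeatures = featurizeAtoms(mol, atomTypes))
}

#' Build MolecularGraphs for a vector of standardized SMILES
#'
#' @param smilesStd character vector of standardized SMILES.
#' @param atomTypes atom-type slots, see [featurizeAtoms()].
#' @return named list of [MolecularGraph-class] objects.
#' @export
molecularGraphs <- function(smilesStd, atomTypes = defaultAtomTypes()) {
  out <- lapply(smilesStd, molecularGraph, atomTypes = atomTypes)
  names(out) <- names(smilesStd)
  out
}
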