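## Experiment orchestration: wires standardization, fingerprint generation,
## the regression benchmark (VS I), pairwise CKA (VS II) and class-based
## clustering (VS III) into single entry points with a run manifest.

#' Configuration for the three benchmark experiments
#'
#' All seeds are explicit; every quantity defaults to the desk-scale
#' synthetic study. Supply `smilesFile` (.smi) and/or `tuplesFile` (CSV with
#' drug_a, drug_b, cell_line, replicate and the five score columns) to run
#' on real data instead of the synthetic generators.
#'
#' @param seed master seed.
#' @param nMolecules,nCellLines,nTuples,signalFraction synthetic study size
#'   and planted signal fraction (see [screenSpec()]).
#' @param fingerprints tags among `"morgan300"`, `"morgan1024"`,
#'   `"topo1024"`, `"gae16"`, `"gae64"`, `"vae16"`.
#' @param split,folds,repeats cross-validation protocol for VS I.
#' @param gaeEpochs,gaeFolds GAE training schedule (desk scale).
#' @param vaeEpochs,vaeFolds,vaeHidden,vaeMaxLen VAE training schedule.
#' @param smilesFile,tuplesFile optional real input files.
#' @param classes number of classes for VS III.
#' @return list of class `fpbenchConfig`.
#' @export
fpbenchConfig <- function(seed = 1L, nMolecules = 60L, nCellLines = 5L,
                          nTuples = 600L, signalFraction = 0.5,
                          fingerprints = c("morgan300", "topo1024", "gae64"),
                          split = "90:10", folds = 10L, repeats = 1L,
                          gaeEpochs = 5L, gaeFolds = 2L,
                          vaeEpochs = 2L, vaeFolds = 1L, vaeHidden = 64L,
                          vaeMaxLen = 140L,
                          smilesFile = NULL, tuplesFile = NULL,
                          classes = 10L) {
  structure(as.list(environment()), class = "fpbenchConfig")
}

runManifest <- function(config) {
  tmp <- tempfile()
  writeLines(deparse(config[order(names(config))]), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(configHash = hash, seed = config$seed,
       packageVersion = as.character(utils::packageVersion("fpbench")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

prepareCompounds <- function(config) {
  if (!is.null(config$smilesFile)) {
    if (!file.exists(config$smilesFile))
      stop("input file not found: ", config$smilesFile)
    mols <- readSmiFile(config$smilesFile)
    mols$family <- NULL
  } else {
    mols <- genMolecules(config$nMolecules, seed = config$seed)
  }
  rec <- standardizeMolecules(mols$smiles, mols$id)
  acc <- filterByLength(rec)
  keep <- mols[match(acc$id, mols$id), , drop = FALSE]
  keep$smiles_std <- acc$smiles_std
  keep
}

buildFingerprints <- function(compounds, config) {
  fps <- list()
  tags <- config$fingerprints
  smi <- compounds$smiles_std
  ids <- compounds$id
  for (tag in intersect(tags, c("morgan300", "morgan1024", "topo1024")))
    fps[[tag]] <- ruleFingerprintMatrix(smi, ids, tag)
  if (any(c("gae16", "gae64") %in% tags)) {
    graphs <- molecularGraphs(stats::setNames(smi, ids))
    gm <- trainGAE(graphs, gaeConfig(epochs = config$gaeEpochs,
                                     folds = config$gaeFolds,
                                     seed = config$seed))
    for (tag in intersect(tags, c("gae16", "gae64")))
      fps[[tag]] <- gaeFingerprintMatrix(graphs, gm$weights, tag)
  }
  if ("vae16" %in% tags) {
    vm <- trainVAE(smi, vaeConfig(latentDim = 16L,
                                  maxLen = config$vaeMaxLen,
                                  gruHidden = config$vaeHidden,
                                  epochs = config$vaeEpochs,
                                  folds = config$vaeFolds,
                                  seed = config$seed))
    fps[["vae16"]] <- vaeFingerprintMatrix(smi, ids, vm)
  }
  fps
}

loadTuples <- function(config, compounds) {
  if (!is.null(config$tuplesFile)) {
    if (!file.exists(config$tuplesFile))
      stop("input file not found: ", config$tuplesFile)
    read.csv(config$tuplesFile, stringsAsFactors = FALSE)
  } else {
    genScreen(compounds,
              screenSpec(nCellLines = config$nCellLines,
                         nTuples = config$nTuples,
                         signalFraction = config$signalFraction,
                         seed = config$seed))$tuples
  }
}

#' Run the drug-combination regression benchmark (VS I)
#'
#' Standardizes/simulates compounds, builds the configured fingerprints,
#' assembles the combination screen and benchmarks every fingerprint on all
#' five response scores.
#'
#' @param config an [fpbenchConfig()].
#' @param regressor fit/predict pair (default [xgbRegressor()]).
#' @return list with `results` (benchmark table), `manifest`.
#' @export
runVS1 <- function(config = fpbenchConfig(), regressor = xgbRegressor()) {
  compounds <- prepareCompounds(config)
  fps <- buildFingerprints(compounds, config)
  tuples <- loadTuples(config, compounds)
  res <- benchmarkFingerprints(fps, tuples, regressor, split = config$split,
                               k = config$folds, repeats = config$repeats,
                               seed = config$seed)
  list(results = res, manifest = runManifest(config))
}

#' Run the pairwise fingerprint-similarity experiment (VS II)
#'
#' @param config an [fpbenchConfig()].
#' @param estimator HSIC estimator for [pairwiseCKA()].
#' @return list with `similarity`, `distance`, `order`, `manifest`.
#' @export
runVS2 <- function(config = fpbenchConfig(), estimator = "unbiased") {
  compounds <- prepareCompounds(config)
  fps <- buildFingerprints(compounds, config)
  pw <- pairwiseCKA(fps, estimator = estimator)
  c(pw[c("similarity", "distance", "order")],
    list(manifest = runManifest(config)))
}

#' Run the class-based clustering evaluation (VS III)
#'
#' @param config an [fpbenchConfig()].
#' @return list with `scores` (ranked table), `labels`, `manifest`.
#' @export
runVS3 <- function(config = fpbenchConfig()) {
  compounds <- prepareCompounds(config)
  fps <- buildFingerprints(compounds, config)
  labels <- genClassLabels(compounds, K = config$classes, seed = config$seed)
  lab <- labels$class[match(compounds$id, labels$drug_id)]
  scores <- scoreTable(fps, lab)
  list(scores = scores, labels = labels, manifest = runManifest(config))
}
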