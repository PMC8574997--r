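## Drug-combination regression benchmark: tuple aggregation, pair
## featurization, repeated cross-validation with a pluggable regressor,
## Fisher-z confidence intervals for the Pearson correlation and
## bootstrap intervals for the SD-normalized RMSE.

SCORE_COLS <- c("css", "bliss", "hsa", "loewe", "zip")

#' Aggregate raw combination tuples
#'
#' Canonicalizes each drug pair by sorted compound id (so (A,B) and (B,A)
#' rows collapse) and averages the five response scores over biological
#' replicates within each (pair, cell line) key.
#'
#' @param tuples data.frame with columns `drug_a`, `drug_b`, `cell_line`,
#'   optionally `replicate`, and the five score columns `css`, `bliss`,
#'   `hsa`, `loewe`, `zip`.
#' @param orderMode `"canonical"` (default; collapse both orders) or
#'   `"keep"` (average replicates only, preserving the given order).
#' @return aggregated data.frame, one row per (drug_a, drug_b, cell_line).
#' @export
aggregateTuples <- function(tuples, orderMode = c("canonical", "keep")) {
  orderMode <- match.arg(orderMode)
  stopifnot(all(c("drug_a", "drug_b", "cell_line", SCORE_COLS) %in% names(tuples)))
  for (s in SCORE_COLS)
    if (!is.numeric(tuples[[s]]))
      stop("non-numeric entries in score column '", s, "'")
  if (any(tuples$drug_a == tuples$drug_b))
    stop("self-combinations (drug_a == drug_b) are not allowed")
  a <- tuples$drug_a; b <- tuples$drug_b
  if (orderMode == "canonical") {
    swap <- a > b
    tuples$drug_a <- ifelse(swap, b, a)
    tuples$drug_b <- ifelse(swap, a, b)
  }
  agg <- aggregate(tuples[SCORE_COLS],
                   by = tuples[c("drug_a", "drug_b", "cell_line")],
                   FUN = mean)
  agg <- agg[order(agg$drug_a, agg$drug_b, agg$cell_line), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Featurize one drug combination
#'
#' Default: concatenation of the two fingerprints (drugs already in
#' canonical id order) and the cell-line one-hot, length `2n + n_cells`.
#' Path-based (topological) fingerprints are bit-averaged instead:
#' elementwise mean of the two vectors, length `n + n_cells`.
#'
#' @param fpA,fpB fingerprint vectors of equal length, drug order already
#'   canonical.
#' @param cellOnehot one-hot vector over the fixed cell-line dictionary.
#' @param fpSubtype fingerprint subtype; `"path"` triggers bit-averaging.
#' @return numeric feature vector.
#' @export
featurizeCombination <- function(fpA, fpB, cellOnehot, fpSubtype = "circular-2D") {
  if (length(fpA) != length(fpB)) stop("fingerprint length mismatch")
  if (fpSubtype == "path") c((fpA + fpB) / 2, cellOnehot)
  else c(fpA, fpB, cellOnehot)
}

#' Build the design matrix for a combination dataset
#'
#' @param fp a [FingerprintMatrix-class] covering every drug in `tuples`.
#' @param tuples aggregated tuples from [aggregateTuples()].
#' @param cellLines fixed cell-line dictionary (default: sorted unique
#'   values present).
#' @return list with `X` (n x p design matrix) and `Y` (n x 5 score matrix).
#' @export
featurizeDataset <- function(fp, tuples, cellLines = NULL) {
  V <- fpValues(fp)
  drugs <- unique(c(tuples$drug_a, tuples$drug_b))
  missing <- setdiff(drugs, rownames(V))
  if (length(missing))
    stop("alignment error: drugs absent from fingerprint matrix: ",
         paste(head(missing, 10), collapse = ", "))
  if (is.null(cellLines)) cellLines <- sort(unique(tuples$cell_line))
  unknown <- setdiff(unique(tuples$cell_line), cellLines)
  if (length(unknown))
    stop("unknown cell line(s): ", paste(unknown, collapse = ", "))
  nc <- length(cellLines)
  n <- nrow(tuples)
  subtype <- fpSubtype(fp)
  p <- if (subtype == "path") nBits(fp) + nc else 2L * nBits(fp) + nc
  X <- matrix(0, n, p)
  for (i in seq_len(n)) {
    cellVec <- as.numeric(cellLines == tuples$cell_line[i])
    X[i, ] <- featurizeCombination(V[tuples$drug_a[i], ], V[tuples$drug_b[i], ],
                                   cellVec, subtype)
  }
  list(X = X, Y = as.matrix(tuples[SCORE_COLS]))
}

#' Regressor constructors for the benchmark
#'
#' Pluggable fit/predict pairs. `xgbRegressor()` is the shipped
#' gradient-boosted tree default, `ridgeRegressor()` a linear baseline
#' (glmnet, fixed lambda), `lmRegressor()` ordinary least squares (useful
#' with low-dimensional ideal descriptors).
#'
#' @param nrounds,maxDepth,eta xgboost parameters.
#' @param lambda ridge penalty.
#' @return list with elements `fit(X, y)` and `predict(model, X)`.
#' @name regressors
NULL

#' @rdname regressors
#' @export
xgbRegressor <- function(nrounds = 150L, maxDepth = 6L, eta = 0.1) {
  list(
    fit = function(X, y)
      xgboost::xgboost(data = X, label = y, nrounds = nrounds,
                       max_depth = maxDepth, eta = eta,
                       objective = "reg:squarederror", verbose = 0,
                       nthread = 1L),
    predict = function(model, X) predict(model, X)
  )
}

#' @rdname regressors
#' @export
ridgeRegressor <- function(lambda = 1) {
  list(
    fit = function(X, y) glmnet::glmnet(X, y, alpha = 0, lambda = lambda),
    predict = function(model, X) as.numeric(predict(model, X))
  )
}

#' @rdname regressors
#' @export
lmRegressor <- function() {
  list(
    fit = function(X, y) {
      df <- as.data.frame(X); df$.y <- y
      lm(.y ~ ., data = df)
    },
    predict = function(model, X) as.numeric(predict(model, as.data.frame(X)))
  )
}

#' Repeated cross-validation predictions
#'
#' `"90:10"`: k-fold partition (k = 10 gives 10% test folds), reshuffled per
#' repeat with a derived seed. `"60:40"`: k repeated shuffled 60:40 holdouts
#' per repeat (disjoint folds cannot yield 40% test portions, so repeated
#' holdouts implement the stated split). One model is fit per score column.
#'
#' @param X design matrix; `Y` matrix of targets (one column per score).
#' @param regressor a fit/predict pair, see [regressors].
#' @param split `"90:10"` or `"60:40"`.
#' @param k folds (or holdouts) per repeat.
#' @param repeats number of repeats.
#' @param seed base seed; repeat r uses seed + r.
#' @return list of folds; each fold has `test` (row indices), `truth` and
#'   `pred` (matrices over score columns).
#' @export
runCV <- function(X, Y, regressor, split = c("90:10", "60:40"), k = 10L,
                  repeats = 1L, seed = 1L) {
  split <- match.arg(split)
  Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n, n >= 5L * k)
  out <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    if (split == "90:10") {
      foldId <- sample(rep_len(seq_len(k), n))
      testSets <- lapply(seq_len(k), function(f) which(foldId == f))
    } else {
      testSets <- lapply(seq_len(k), function(f) sample(n, round(0.4 * n)))
    }
    for (testIdx in testSets) {
      trainIdx <- setdiff(seq_len(n), testIdx)
      pred <- matrix(NA_real_, length(testIdx), ncol(Y),
                     dimnames = list(NULL, colnames(Y)))
      for (s in seq_len(ncol(Y))) {
        ytr <- Y[trainIdx, s]
        if (sd(ytr) == 0 || sd(Y[testIdx, s]) == 0)
          warning("degenerate fold: constant target '", colnames(Y)[s], "'")
        model <- regressor$fit(X[trainIdx, , drop = FALSE], ytr)
        pred[, s] <- regressor$predict(model, X[testIdx, , drop = FALSE])
      }
      out[[length(out) + 1L]] <- list(test = testIdx,
                                      truth = Y[testIdx, , drop = FALSE],
                                      pred = pred)
    }
  }
  out
}

#' Fisher-z t confidence interval for fold-wise Pearson correlations
#'
#' Each fold correlation is Fisher z-transformed, a Student-t interval
#' (df = folds - 1) is formed on the z scale and its endpoints are
#' back-transformed. Reports the mean fold PCC and the interval halfwidth.
#' A fold with |r| = 1 has an infinite z value and is reported as
#' degenerate with a warning.
#'
#' @param foldPccs numeric vector of per-fold correlations (>= 2).
#' @param conf confidence level (0.95).
#' @return list with `mean`, `halfwidth`, `lower`, `upper`, `degenerate`.
#' @export
pccCI <- function(foldPccs, conf = 0.95) {
  stopifnot(length(foldPccs) >= 2L)
  if (any(abs(foldPccs) >= 1)) {
    warning("fold PCC of magnitude 1: Fisher z is infinite, CI degenerate")
    return(list(mean = mean(foldPccs), halfwidth = NA_real_,
                lower = NA_real_, upper = NA_real_, degenerate = TRUE))
  }
  z <- atanh(foldPccs)
  nf <- length(z)
  mz <- mean(z)
  se <- sd(z) / sqrt(nf)
  hw <- qt(1 - (1 - conf) / 2, df = nf - 1L) * se
  lo <- tanh(mz - hw); hi <- tanh(mz + hw)
  list(mean = mean(foldPccs), halfwidth = (hi - lo) / 2,
       lower = lo, upper = hi, degenerate = FALSE)
}

#' SD-normalized RMSE
#'
#' RMSE divided by the population (n-denominator) standard deviation of the
#' target, so the constant-mean predictor scores exactly 1.
#'
#' @param yTrue,yPred numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
nrmse <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) >= 3L)
  s <- sqrt(mean((yTrue - mean(yTrue))^2))
  if (s == 0) stop("zero target standard deviation")
  sqrt(mean((yTrue - yPred)^2)) / s
}

#' Empirical-bootstrap confidence interval for the normalized RMSE
#'
#' Paired resampling with `B` iterations; the symmetric 95% interval is
#' plus/minus the 97.5th percentile of the absolute bootstrap deviations
#' from the point estimate.
#'
#' @param yTrue,yPred numeric vectors of equal length (>= 3).
#' @param B bootstrap iterations (1000).
#' @param seed RNG seed.
#' @return list with `nrmse` and `halfwidth`.
#' @export
nrmseCI <- function(yTrue, yPred, B = 1000L, seed = 1L) {
  point <- nrmse(yTrue, yPred)
  set.seed(seed)
  n <- length(yTrue)
  dev <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    nrmse(yTrue[idx], yPred[idx]) - point
  }, numeric(1))
  list(nrmse = point, halfwidth = unname(quantile(abs(dev), 0.975)))
}

#' Shapiro-Wilk normality gate
#'
#' Applied to the Fisher-z-transformed fold correlations before the
#' t-interval; p < 0.05 emits a warning but does not block the interval.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `p`, `pass`, `degenerate`.
#' @export
shapiroGate <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(values) == 0) {
    warning("constant input: normality test degenerate")
    return(list(p = NA_real_, pass = NA, degenerate = TRUE))
  }
  p <- shapiro.test(values)$p.value
  if (p < 0.05)
    warning(sprintf("normality assumption questionable (Shapiro-Wilk p = %.3g)", p))
  list(p = p, pass = p >= 0.05, degenerate = FALSE)
}

#' Benchmark fingerprints on a combination screen
#'
#' For every (fingerprint x score) pair: featurize, run repeated CV with the
#' supplied regressor, compute per-fold test correlations, the Fisher-z
#' interval (with the Shapiro-Wilk gate on the z values), and the pooled
#' bootstrap normalized RMSE. The best fingerprint per score (highest mean
#' PCC) is flagged.
#'
#' @param fps named list of [FingerprintMatrix-class] objects.
#' @param tuples raw or aggregated combination tuples.
#' @param regressor fit/predict pair (default [xgbRegressor()]).
#' @param split,k,repeats,seed cross-validation protocol, see [runCV()].
#' @param cellLines fixed cell-line dictionary (default from data).
#' @return data.frame of benchmark results, one row per fingerprint x score.
#' @export
benchmarkFingerprints <- function(fps, tuples, regressor = xgbRegressor(),
                                  split = "90:10", k = 10L, repeats = 1L,
                                  seed = 1L, cellLines = NULL) {
  stopifnot(length(fps) >= 1L, !is.null(names(fps)))
  agg <- aggregateTuples(tuples)
  rows <- list()
  for (fpName in names(fps)) {
    ds <- featurizeDataset(fps[[fpName]], agg, cellLines)
    folds <- runCV(ds$X, ds$Y, regressor, split = split, k = k,
                   repeats = repeats, seed = seed)
    for (s in SCORE_COLS) {
      rs <- vapply(folds, function(f) cor(f$truth[, s], f$pred[, s]), numeric(1))
      ci <- pccCI(rs)
      gate <- if (all(abs(rs) < 1)) shapiroGate(atanh(rs))
              else list(p = NA_real_, pass = NA, degenerate = TRUE)
      yT <- unlist(lapply(folds, function(f) f$truth[, s]))
      yP <- unlist(lapply(folds, function(f) f$pred[, s]))
      nr <- nrmseCI(yT, yP, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        fingerprint = fpName, score = s, split = split, folds = k,
        repeats = repeats, seed = seed,
        pcc_mean = ci$mean, pcc_ci_halfwidth = ci$halfwidth,
        nrmse = nr$nrmse, nrmse_ci_halfwidth = nr$halfwidth,
        shapiro_p = gate$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$best <- FALSE
  for (s in SCORE_COLS) {
    sub <- which(res$score == s)
    res$best[sub[which.max(res$pcc_mean[sub])]] <- TRUE
  }
  res
}
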