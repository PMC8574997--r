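mkTuples <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("tuple aggregation averages replicates and canonicalizes pairs", {
  raw <- mkTuples(drug_a = c("A", "A", "B"), drug_b = c("B", "B", "A"),
                  cell_line = "c1", replicate = c(1L, 2L, 1L),
                  css = c(2, 4, 6), bliss = c(1, 1, 1), hsa = 0,
                  loewe = c(2, 4, 6), zip = 1)
  agg <- aggregateTuples(raw)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$loewe, 4)       # mean of 2, 4, 6 over both orders
  expect_equal(agg$drug_a, "A")
  # replicate-free input is unchanged except key canonicalization
  raw2 <- mkTuples(drug_a = c("B", "A"), drug_b = c("A", "C"),
                   cell_line = c("c1", "c2"), replicate = 1L,
                   css = c(1, 2), bliss = c(3, 4), hsa = c(5, 6),
                   loewe = c(7, 8), zip = c(9, 10))
  agg2 <- aggregateTuples(raw2)
  expect_equal(nrow(agg2), 2L)
  expect_equal(agg2$drug_a, c("A", "A"))
  expect_equal(agg2$drug_b, c("B", "C"))
  expect_equal(sort(agg2$css), c(1, 2))
  expect_error(aggregateTuples(mkTuples(drug_a = "A", drug_b = "A",
                                        cell_line = "c", replicate = 1L,
                                        css = 1, bliss = 1, hsa = 1,
                                        loewe = 1, zip = 1)), "self-comb")
})

test_that("combination featurization: concat default, path bit-averaging", {
  fpA <- rep(1, 300); fpB <- rep(0, 300); cell <- c(0, 1, 0, 0, 0)
  v <- featurizeCombination(fpA, fpB, cell)
  expect_length(v, 605L)
  vt <- featurizeCombination(rep(1, 1024), rep(0, 1024), cell, "path")
  expect_length(vt, 1029L)
  expect_equal(vt[1:1024], rep(0.5, 1024))
  # identical fingerprints: averaged block equals either input
  same <- featurizeCombination(fpA, fpA, cell, "path")
  expect_equal(same[1:300], fpA)
  expect_error(featurizeCombination(rep(1, 10), rep(1, 9), cell), "mismatch")
})

test_that("cross-validation folds partition and reproduce under a seed", {
  set.seed(1)
  X <- matrix(rnorm(100 * 3), 100)
  Y <- matrix(rnorm(500), 100, 5,
              dimnames = list(NULL, c("css", "bliss", "hsa", "loewe", "zip")))
  reg <- lmRegressor()
  f1 <- runCV(X, Y, reg, split = "90:10", k = 10L, seed = 3L)
  expect_length(f1, 10L)
  expect_true(all(vapply(f1, function(f) length(f$test), integer(1)) == 10L))
  expect_equal(sort(unlist(lapply(f1, `[[`, "test"))), 1:100)
  f2 <- runCV(X, Y, reg, split = "90:10", k = 10L, seed = 3L)
  expect_identical(lapply(f1, `[[`, "test"), lapply(f2, `[[`, "test"))
  h <- runCV(X, Y, reg, split = "60:40", k = 5L, seed = 3L)
  expect_true(all(vapply(h, function(f) length(f$test), integer(1)) == 40L))
})

test_that("Fisher-z interval matches hand-computed references", {
  ci0 <- pccCI(rep(0, 5))
  expect_equal(ci0$mean, 0)
  expect_equal(ci0$lower, -ci0$upper)
  cIdent <- pccCI(rep(0.42, 6))
  expect_equal(cIdent$halfwidth, 0)
  # frozen arithmetic oracle for folds {0.5, 0.6, 0.7}
  ci <- pccCI(c(0.5, 0.6, 0.7))
  expect_equal(ci$mean, 0.6)
  expect_equal(ci$lower, 0.2983274632, tolerance = 1e-9)
  expect_equal(ci$upper, 0.8000747298, tolerance = 1e-9)
  expect_equal(ci$halfwidth, 0.2508736333, tolerance = 1e-9)
  expect_warning(bad <- pccCI(c(1, 0.5)), "degenerate")
  expect_true(bad$degenerate)
})

test_that("normalized RMSE: mean-predictor identity, zero, scale invariance", {
  set.seed(2)
  for (i in 1:5) {
    y <- rnorm(40, sd = runif(1, 0.5, 20))
    expect_true(nrmse(y, rep(mean(y), 40)) == 1)
  }
  y <- rnorm(30)
  expect_equal(nrmse(y, y), 0)
  p <- y + rnorm(30, sd = 0.3)
  expect_equal(nrmse(3.7 * y, 3.7 * p), nrmse(y, p), tolerance = 1e-12)
  expect_error(nrmse(rep(1, 10), rnorm(10)), "zero target")
})

test_that("bootstrap interval is symmetric, reproducible, non-negative", {
  set.seed(3)
  y <- rnorm(60); p <- y + rnorm(60, sd = 0.5)
  ci <- nrmseCI(y, p, B = 200L, seed = 9L)
  expect_gte(ci$halfwidth, 0)
  expect_identical(ci, nrmseCI(y, p, B = 200L, seed = 9L))
})

test_that("the normality gate warns on skew and flags degenerate input", {
  set.seed(4)
  g <- shapiroGate(rnorm(50))
  expect_gt(g$p, 0.05)
  expect_true(g$pass)
  expect_warning(gs <- shapiroGate(rexp(200)), "normality")
  expect_lt(gs$p, 0.05)
  expect_warning(gd <- shapiroGate(rep(1, 10)), "degenerate")
  expect_true(gd$degenerate)
  expect_error(shapiroGate(c(1, 2)), "3 <= n")
})

test_that("benchmark grid shape and end-to-end drug-order invariance", {
  keep <- fxAccepted()
  sc <- genScreen(keep, screenSpec(nCellLines = 3L, nTuples = 150L,
                                   signalFraction = 0.6, seed = 5L))
  fps <- fxRuleFps()
  res <- benchmarkFingerprints(fps, sc$tuples, ridgeRegressor(),
                               split = "90:10", k = 10L, seed = 5L)
  expect_equal(nrow(res), 2L * 5L)
  expect_equal(sum(res$best), 5L)
  expect_true(all(res$pcc_mean >= -1 & res$pcc_mean <= 1))
  expect_true(all(res$nrmse >= 0))
  # swapping drug_a/drug_b leaves every result unchanged
  swapped <- sc$tuples
  swapped[c("drug_a", "drug_b")] <- swapped[c("drug_b", "drug_a")]
  res2 <- benchmarkFingerprints(fps, swapped, ridgeRegressor(),
                                split = "90:10", k = 10L, seed = 5L)
  expect_equal(res, res2)
  # missing drugs raise an alignment error
  sub <- fpValues(fps$morgan300)[-1, , drop = FALSE]
  fpsBad <- list(m = FingerprintMatrix(sub, "binary", "rule", "circular-2D"))
  expect_error(benchmarkFingerprints(fpsBad, sc$tuples, ridgeRegressor()),
               "alignment error")
})

test_that("measured PCC grows with the planted signal fraction", {
  keep <- fxAccepted()
  for (seed in 1:3) {
    pccs <- vapply(c(0.1, 0.4, 0.8), function(rho) {
      sc <- genScreen(keep, screenSpec(nCellLines = 3L, nTuples = 900L,
                                       signalFraction = rho,
                                       replicateRate = 0,
                                       seed = 40L + seed))
      agg <- aggregateTuples(sc$tuples)
      key <- do.call(paste, sc$truth$tupleKey)
      m <- match(paste(agg$drug_a, agg$drug_b, agg$cell_line), key)
      folds <- runCV(sc$truth$idealDesign[m, ],
                     as.matrix(agg[, "loewe", drop = FALSE]),
                     lmRegressor(), split = "90:10", k = 5L, seed = seed)
      mean(vapply(folds, function(f) cor(f$truth[, 1], f$pred[, 1]),
                  numeric(1)))
    }, numeric(1))
    expect_true(all(diff(pccs) > 0), info = paste("seed", seed))
  }
})
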