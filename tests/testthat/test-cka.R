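test_that("column centering: examples, idempotence, minimum size", {
  expect_equal(centerColumns(matrix(c(1, 3), 2)), matrix(c(-1, 1), 2))
  set.seed(1)
  X <- matrix(rnorm(30), 10)
  Xc <- centerColumns(X)
  expect_equal(colMeans(Xc), numeric(3))
  expect_equal(centerColumns(Xc), Xc)
  expect_error(centerColumns(matrix(1, 1, 2)), "2 rows")
})

test_that("feature-space HSIC is the squared Frobenius cross-product", {
  X <- matrix(c(-1, 1), 2)
  expect_equal(hsicFeature(X, X), 4)
  # zero columns contribute nothing
  expect_equal(hsicFeature(cbind(X, 0), X), 4)
  # orthogonal columns across X and Y give zero cross-covariance
  Y <- centerColumns(matrix(c(1, 1, -1, 1), 2))  # first column centers to 0
  expect_equal(hsicFeature(X, Y[, 1, drop = FALSE]), 0)
  expect_error(hsicFeature(matrix(0, 3, 2), matrix(0, 4, 2)), "mismatch")
})

test_that("sample-space trace form equals the feature form when centered", {
  set.seed(2)
  for (i in 1:5) {
    X <- centerColumns(matrix(rnorm(18), 6, 3))
    Y <- centerColumns(matrix(rnorm(24), 6, 4))
    f <- hsicFeature(X, Y)
    s <- hsicSample(X, Y)
    expect_lt(abs(f - s) / max(f, 1e-12), 1e-9)
  }
  expect_equal(hsicSample(matrix(0, 4, 2), matrix(0, 4, 3)), 0)
})

test_that("unbiased estimator: minimum m, null behavior, self-similarity", {
  expect_error(hsicUnbiased(diag(3), diag(3)), "m = 4")
  set.seed(3)
  X <- centerColumns(matrix(rnorm(60), 20))
  Kx <- tcrossprod(X)
  expect_gt(hsicUnbiased(Kx, Kx), 0)
  # Monte-Carlo mean near zero for independent inputs
  h <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    A <- centerColumns(matrix(rnorm(50 * 4), 50))
    B <- centerColumns(matrix(rnorm(50 * 4), 50))
    hsicUnbiased(tcrossprod(A), tcrossprod(B))
  }, numeric(1))
  expect_lt(abs(mean(h)), 3 * sd(h) / sqrt(length(h)))
})

test_that("CKA attains 1 on self and is invariant to scale and rotation", {
  set.seed(4)
  X <- matrix(rnorm(50 * 12), 50)
  expect_equal(ckaValue(cka(X, X)), 1, tolerance = 1e-12)
  expect_equal(ckaValue(cka(X, -2.5 * X)), 1, tolerance = 1e-9)
  Q <- qr.Q(qr(matrix(rnorm(144), 12)))
  expect_equal(ckaValue(cka(X, X %*% Q)), 1, tolerance = 1e-9)
  expect_error(cka(X, matrix(7, 50, 3)), "undefined similarity")
})

test_that("CKA is symmetric, bounded, and matches the RV coefficient", {
  set.seed(5)
  for (i in 1:20) {
    m <- sample(12:40, 1)
    X <- matrix(rnorm(m * sample(3:20, 1)), m)
    Y <- if (i %% 2) matrix(rbinom(m * 8, 1, 0.3), m)  # mixed binary pair
         else matrix(rnorm(m * sample(3:20, 1)), m)
    if (sd(as.numeric(Y)) == 0) Y[1, 1] <- 1
    r1 <- cka(X, Y); r2 <- cka(Y, X)
    expect_identical(ckaValue(r1), ckaValue(r2))
    expect_gte(ckaValue(r1), 0)
    expect_lte(ckaValue(r1), 1 + 1e-9)
    # RV coefficient as independent oracle (biased/plug-in estimator)
    Xc <- centerColumns(X); Yc <- centerColumns(Y)
    rv <- sum(tcrossprod(Xc) * tcrossprod(Yc)) /
      sqrt(sum(tcrossprod(Xc)^2) * sum(tcrossprod(Yc)^2))
    expect_equal(ckaValue(cka(X, Y, estimator = "biased")), rv,
                 tolerance = 1e-9)
    # biased estimator: feature and sample modes agree
    bf <- ckaValue(cka(X, Y, estimator = "biased", mode = "feature"))
    bs <- ckaValue(cka(X, Y, estimator = "biased", mode = "sample"))
    expect_lt(abs(bf - bs), 1e-9)
  }
})

test_that("the auto mode rule follows compounds vs bits", {
  set.seed(6)
  X <- matrix(rnorm(30 * 5), 30); Y <- matrix(rnorm(30 * 4), 30)
  expect_equal(cka(X, Y, estimator = "biased")@mode, "feature")
  Xw <- matrix(rnorm(10 * 40), 10); Yw <- matrix(rnorm(10 * 4), 10)
  expect_equal(cka(Xw, Yw, estimator = "biased")@mode, "sample")
})

test_that("pairwise CKA: duplicates, diagonal, alignment checks", {
  set.seed(7)
  ids <- paste0("d", 1:25)
  X <- matrix(rnorm(25 * 6), 25, dimnames = list(ids, NULL))
  Y <- matrix(rnorm(25 * 9), 25, dimnames = list(ids, NULL))
  pw <- pairwiseCKA(list(a = X, b = X, c = Y))
  expect_equal(pw$similarity["a", "b"], 1, tolerance = 1e-9)
  expect_equal(diag(pw$similarity), c(a = 1, b = 1, c = 1))
  expect_equal(pw$similarity, t(pw$similarity))
  expect_length(pw$order, 3L)
  Z <- matrix(rnorm(25 * 3), 25, dimnames = list(paste0("x", 1:25), NULL))
  expect_error(pairwiseCKA(list(a = X, b = Z)), "compound-set mismatch")
})
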