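test_that("z-scoring: population sd, idempotence, constant columns", {
  expect_equal(zscoreNormalize(matrix(c(0, 2), 2)), matrix(c(-1, 1), 2))
  set.seed(1)
  X <- matrix(rnorm(60, sd = 4), 20)
  Xz <- zscoreNormalize(X)
  expect_equal(colMeans(Xz), numeric(3))
  expect_equal(zscoreNormalize(Xz), Xz, tolerance = 1e-12)
  expect_warning(Xd <- zscoreNormalize(cbind(X, 5)), "constant")
  expect_equal(ncol(Xd), 3L)
  expect_error(zscoreNormalize(matrix(1, 4, 2)), "constant")
})

test_that("PCA keeps the smallest component set above 0.95 variance", {
  set.seed(2)
  # rank-1 structure
  u <- rnorm(30)
  X1 <- zscoreNormalize(outer(u, c(1, 2, 3)) +
                          matrix(rnorm(90, sd = 1e-6), 30))
  expect_equal(ncol(pcaReduce(X1)), 1L)
  # isotropic 3-d Gaussian: all three components needed
  X3 <- zscoreNormalize(matrix(rnorm(3000), 1000))
  expect_equal(ncol(pcaReduce(X3)), 3L)
  X <- zscoreNormalize(matrix(rnorm(200), 20))
  expect_lte(ncol(pcaReduce(X)), min(dim(X)))
})

test_that("PLS with labels as targets sharpens separable structure", {
  set.seed(3)
  n <- 60
  lab <- rep(c("a", "b", "c"), each = n / 3)
  centers <- matrix(rnorm(3 * 5, sd = 3), 3)
  X <- centers[as.integer(factor(lab)), ] + matrix(rnorm(n * 5), n)
  X <- cbind(X, matrix(rnorm(n * 20), n))  # noise features
  Xz <- zscoreNormalize(X)
  P <- plsReduce(Xz, lab)
  expect_equal(dim(P), c(n, 2L))
  silZ <- mean(vapply(unique(lab), function(k)
    silhouetteMean(ldaOneVsAll(Xz, lab)[[k]], factor(lab == k)), numeric(1)))
  silP <- mean(vapply(unique(lab), function(k)
    silhouetteMean(ldaOneVsAll(P, lab)[[k]], factor(lab == k)), numeric(1)))
  expect_gt(silP, 0.5)
  # permuted labels destroy the projection's class structure
  labPerm <- sample(lab)
  Pp <- plsReduce(Xz, labPerm)
  silPerm <- mean(vapply(unique(lab), function(k)
    silhouetteMean(ldaOneVsAll(Pp, labPerm)[[k]], factor(labPerm == k)),
    numeric(1)))
  expect_lt(silPerm, silP / 2)
  expect_error(plsReduce(Xz, lab, nComponents = 1000L), "exceeds")
})

test_that("one-vs-all discriminants separate separable blobs", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40, mean = 0), 20),
             matrix(rnorm(40, mean = 8), 20))
  lab <- rep(c("a", "b"), each = 20)
  pr <- ldaOneVsAll(X, lab)
  expect_length(pr, 2L)
  p <- pr[["a"]]
  expect_true(max(p[lab == "a"]) < min(p[lab == "b"]) ||
                min(p[lab == "a"]) > max(p[lab == "b"]))
  # identical class distributions: near-zero separation
  X0 <- matrix(rnorm(200 * 2), 200)
  lab0 <- rep(c("a", "b"), 100)
  s0 <- silhouetteMean(ldaOneVsAll(X0, lab0)[["a"]], lab0)
  expect_lt(abs(s0), 0.25)
  expect_error(ldaOneVsAll(X, c("a", rep("b", 39))), ">= 2 members")
})

test_that("silhouette matches the worked 4-point instance and brute force", {
  x <- c(0, 1, 4, 6)
  lab <- c("u", "u", "v", "v")
  expect_equal(silhouetteMean(x, lab), 0.6537, tolerance = 1e-4)
  # degenerate: coincident points in different clusters score 0
  expect_equal(silhouetteMean(c(2, 2), c("a", "b")), 0)
  # far-separated clusters approach 1
  expect_gt(silhouetteMean(c(0, 0.01, 1000, 1000.01),
                           c("a", "a", "b", "b")), 0.99)
  # brute-force equivalence on random 1D instances
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    lab <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("a", "b")
    expect_equal(silhouetteMean(x, lab), bruteSilhouette(x, lab),
                 tolerance = 1e-12)
  }
  expect_error(silhouetteMean(1:4, rep("a", 4)), "2 clusters")
})

test_that("silhouette agrees with the cluster package on 1D data", {
  set.seed(6)
  x <- rnorm(25)
  lab <- sample(1:3, 25, replace = TRUE)
  sil <- cluster::silhouette(lab, dist(x))
  expect_equal(silhouetteMean(x, lab), mean(sil[, "sil_width"]),
               tolerance = 1e-12)
})

test_that("variance ratio criterion: worked instance and conventions", {
  expect_equal(vrc(c(0, 1, 4, 6), c("u", "u", "v", "v")), 16.2,
               tolerance = 1e-9)
  perfect <- vrc(c(1, 1, 5, 5), c("a", "a", "b", "b"))
  expect_true(is.infinite(perfect))
  expect_true(isTRUE(attr(perfect, "perfect")))
  # random labels: VRC near 1 in expectation
  set.seed(7)
  vs <- vapply(1:200, function(i) {
    x <- rnorm(40)
    as.numeric(vrc(x, sample(c("a", "b"), 40, replace = TRUE)))
  }, numeric(1))
  expect_gt(mean(vs), 0.7)
  expect_lt(mean(vs), 1.4)
})

test_that("scores are invariant to relabeling cluster ids", {
  set.seed(8)
  x <- rnorm(30)
  lab <- sample(c("a", "b", "c"), 30, replace = TRUE)
  relab <- c(a = "z3", b = "z1", c = "z2")[lab]
  expect_equal(silhouetteMean(x, lab), silhouetteMean(x, relab))
  expect_equal(vrc(x, lab), vrc(x, relab))
})

test_that("score table scales per regime and ranks planted structure first", {
  keep <- fxAccepted()
  fpM <- fxRuleFps()$morgan300
  set.seed(9)
  noise <- matrix(rnorm(nrow(keep) * 24), nrow(keep), 24,
                  dimnames = list(keep$id, NULL))
  fps <- list(morgan = fpM,
              noise = FingerprintMatrix(noise, "continuous", "data",
                                        "sequence"))
  labs <- genClassLabels(keep, K = 8L)
  lab <- labs$class[match(keep$id, labs$drug_id)]
  st <- suppressWarnings(scoreTable(fps, lab))
  expect_equal(nrow(st), 6L)  # 2 fingerprints x 3 regimes
  for (reg in unique(st$preprocessing)) {
    sub <- st[st$preprocessing == reg, ]
    expect_setequal(sub$silhouette_scaled, c(0, 1))
    expect_setequal(sub$vrc_scaled, c(0, 1))
  }
  expect_equal(st$rank[st$fingerprint == "morgan"][1], 1L)
  # a fingerprint identical to another gets identical scaled scores
  st2 <- suppressWarnings(scoreTable(list(a = fpM, b = fpM, n = fps$noise),
                                     lab))
  a <- st2[st2$fingerprint == "a", c("silhouette_scaled", "vrc_scaled")]
  b <- st2[st2$fingerprint == "b", c("silhouette_scaled", "vrc_scaled")]
  expect_equal(a, b, ignore_attr = TRUE)
  expect_error(scoreTable(fps["morgan"], lab), ">= 2")
})
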