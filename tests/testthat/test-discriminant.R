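test_that("region feature matrix holds pooled region levels per sample", {
  pos <- seq(1000, by = 40, length.out = 10)
  methM <- cbind(a = rep(1L, 10), b = rep(9L, 10))
  covM <- matrix(12L, 10, 2)
  me <- makeME(pos, rep("CG", 10), methM, covM, samples = c("a", "b"))
  regions <- data.frame(chrom = "Chr1", start = 1000, end = 1360,
                        context = "CG")
  X <- regionFeatureMatrix(regions, me)
  expect_equal(dim(X), c(2L, 1L))
  expect_equal(unname(X["a", 1]), 1 / 12)
  expect_equal(unname(X["b", 1]), 9 / 12)

  # a region with zero coverage in one sample is dropped
  covM2 <- covM; covM2[, 1] <- 0L; methM2 <- methM; methM2[, 1] <- 0L
  me2 <- makeME(pos + 5000, rep("CG", 10), methM2, covM2,
                samples = c("a", "b"))
  regions2 <- rbind(regions,
                    data.frame(chrom = "Chr1", start = 6000, end = 6360,
                               context = "CG"))
  expect_message(X2 <- regionFeatureMatrix(
    regions2, makeME(c(pos, pos + 5000), rep("CG", 20),
                     rbind(methM, methM2), rbind(covM, covM2),
                     samples = c("a", "b"))), "dropped")
  expect_equal(ncol(X2), 1L)
})

test_that("PCA scores match a direct eigendecomposition of the
           covariance", {
  # collinear points put all variance on PC1
  Xc <- cbind(c(0, 1, 2), c(0, 1, 2))
  pc <- suppressWarnings(pcaReduce(Xc, 2))
  expect_equal(pc$varianceFractions[1], 1)

  # constant columns contribute nothing
  X0 <- cbind(rnorm(6), 5, rnorm(6))
  pc0 <- suppressWarnings(pcaReduce(X0, 2))
  expect_equal(pc0$rotation[2, ], c(0, 0), ignore_attr = TRUE,
               tolerance = 1e-12)

  set.seed(10)
  X <- matrix(rnorm(6 * 50), 6, 50)
  pc4 <- pcaReduce(X, 4)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  ctr <- scale(X, center = TRUE, scale = FALSE)
  for (j in 1:4) {
    oracle <- drop(ctr %*% ev$vectors[, j])
    # equality up to sign
    err <- min(max(abs(pc4$scores[, j] - oracle)),
               max(abs(pc4$scores[, j] + oracle)))
    expect_lt(err, 1e-8)
    expect_equal(pc4$varianceFractions[j],
                 ev$values[j] / sum(ev$values), tolerance = 1e-10)
  }
  # deterministic sign: the largest-magnitude loading is positive
  for (j in 1:4)
    expect_gt(pc4$rotation[which.max(abs(pc4$rotation[, j])), j], 0)
  expect_warning(pcaReduce(X, 10), "clipped")
})

test_that("discriminant axes recover axis-aligned separation and match
           the classic solution", {
  set.seed(3)
  X <- rbind(cbind(rnorm(200, 0, 0.3), rnorm(200, 0, 0.3)),
             cbind(rnorm(200, 8, 0.3), rnorm(200, 0, 0.3)))
  labels <- rep(c("A", "B"), each = 200)
  fit <- ldaFit(X, labels, nFunctions = 1)
  v <- fit$scaling[, 1] / sqrt(sum(fit$scaling[, 1]^2))
  expect_gt(abs(v[1]), 0.99)  # LD1 collinear with the separating axis

  # against MASS::lda (shrinkage disabled to match the classic estimator)
  fit0 <- ldaFit(X, labels, nFunctions = 1, shrinkage = 0)
  ml <- MASS::lda(X, grouping = labels)
  v0 <- fit0$scaling[, 1] / sqrt(sum(fit0$scaling[, 1]^2))
  vm <- ml$scaling[, 1] / sqrt(sum(ml$scaling[, 1]^2))
  expect_gt(abs(sum(v0 * vm)), 0.9999)

  # three identical-mean groups: no between-group signal
  set.seed(8)
  Xn <- matrix(rnorm(30), 15, 2)
  fitn <- ldaFit(Xn, rep(c("A", "B", "C"), each = 5))
  expect_lt(max(fitn$eigenvalues), 2)

  expect_error(ldaFit(X, rep("A", 10)), "two groups")
})

test_that("well-separated groups classify perfectly by nearest
           discriminant centroid", {
  set.seed(6)
  mus <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(g)
    cbind(rnorm(3, mus[g, 1], 0.1), rnorm(3, mus[g, 2], 0.1))))
  labels <- rep(c("g1", "g2", "g3"), each = 3)
  fit <- ldaFit(X, labels, nFunctions = 2)
  pred <- predictLda(fit, X)
  expect_equal(pred, labels)
  # scatter matrices agree with the explicit-loop oracle
  sm <- methylDMA:::.scatterMatrices(X, labels)
  so <- scatterOracle(X, labels)
  expect_equal(sm$H, so$H, tolerance = 1e-10)
  expect_equal(sm$E, so$E, tolerance = 1e-10)
})

test_that("Ward clustering minimizes within-cluster variance on small
           instances", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  w <- wardCluster(x, 2)
  expect_equal(unname(w$labels), c(1, 1, 1, 2, 2, 2))
  # exhaustive check: no 2-partition has lower within-SS
  parts <- allPartitions(6, 2)
  best <- min(apply(parts, 1, function(z) withinSS(x, z)))
  expect_equal(withinSS(x, w$labels), best, tolerance = 1e-10)

  # identical points merge at height zero
  xx <- matrix(1, 4, 2)
  expect_true(all(wardCluster(xx, 2)$heights == 0))

  # three well-separated triplets recover the truth at k = 3
  set.seed(2)
  y <- rbind(matrix(rnorm(6, 0, .1), 3), matrix(rnorm(6, 5, .1), 3),
             matrix(rnorm(6, 10, .1), 3))
  wy <- wardCluster(y, 3)
  expect_equal(adjustedRand(wy$labels, rep(1:3, each = 3)), 1)
  expect_error(wardCluster(y, 10), "exceeds")
})

test_that("Pillai's trace matches MANOVA and respects its bound", {
  # identical observation sets in both groups: statistic 0
  X <- rbind(matrix(rnorm(10), 5, 2), matrix(0, 5, 2))
  X[6:10, ] <- X[1:5, ]
  p0 <- pillaiTrace(X, rep(c("A", "B"), each = 5))
  expect_lt(p0$statistic, 1e-6)

  # near-separated three groups in 2-D approach the bound s = 2
  set.seed(14)
  mus <- rbind(c(0, 0), c(10, 0), c(0, 10))
  Y <- do.call(rbind, lapply(1:3, function(g)
    cbind(rnorm(3, mus[g, 1], 0.01), rnorm(3, mus[g, 2], 0.01))))
  lab <- rep(c("a", "b", "c"), each = 3)
  pp <- pillaiTrace(Y, lab)
  expect_gte(pp$statistic, 1.99)
  expect_lte(pp$statistic, 2)
  expect_lt(pp$p, 1e-6)

  # agreement with the standard MANOVA implementation
  set.seed(15)
  Z <- matrix(rnorm(24), 12, 2) +
    rep(c(0, 1.5, 3), each = 4)
  labZ <- factor(rep(c("a", "b", "c"), each = 4))
  pz <- pillaiTrace(Z, as.character(labZ))
  mv <- summary(stats::manova(Z ~ labZ), test = "Pillai")$stats
  expect_equal(pz$statistic, mv["labZ", "Pillai"], tolerance = 1e-5)
  expect_equal(pz$p, mv["labZ", "Pr(>F)"], tolerance = 1e-4)

  # the bound min(g - 1, p) holds on random inputs
  set.seed(16)
  for (i in 1:10) {
    n <- sample(6:12, 1); p <- sample(2:4, 1)
    W <- matrix(rnorm(n * p), n, p)
    lw <- sample(c("a", "b", "c"), n, TRUE)
    if (length(unique(lw)) < 2) next
    s <- min(length(unique(lw)) - 1, p)
    expect_lte(pillaiTrace(W, lw)$statistic, s + 1e-8)
  }
})

test_that("repeated stratified cross-validation is deterministic and
           scores chance on permuted labels", {
  set.seed(20)
  mus <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  X <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(18, mus[g, ], 0.2), 6, 3, byrow = TRUE)))
  labels <- rep(c("a", "b", "c"), each = 6)

  cv <- crossValidate(X, labels, "lda", repeats = 5, seed = 2)
  expect_equal(cv$mean, 1.0)
  cvs <- crossValidate(X, labels, "svm", repeats = 5, seed = 2)
  expect_equal(cvs$mean, 1.0)

  # same seed, same per-repeat accuracies
  cv2 <- crossValidate(X, labels, "lda", repeats = 5, seed = 2)
  expect_identical(cv$perRepeat, cv2$perRepeat)

  # permutation null: chance level within 3 SE
  cvp <- crossValidate(X, labels, "lda", repeats = 40, seed = 3,
                       permute = TRUE)
  se <- cvp$sd / sqrt(length(cvp$perRepeat))
  expect_lt(abs(cvp$mean - 1 / 3), 3 * se + 0.02)
  expect_error(crossValidate(X[1:3, ], c("a", "b", "c"), "lda"),
               "too small")
})
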