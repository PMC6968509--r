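test_that("centerScale modes behave and replay exactly", {
  set.seed(11)
  X <- matrix(rnorm(80, sd = 3), 10, 8)
  X[, 3] <- 5  # zero-variance column
  ctr <- centerScale(X, "center")
  expect_lt(max(abs(colMeans(ctr$X))), 1e-12)
  expect_equal(applyScaling(ctr$record, X), ctr$X)
  uv <- centerScale(X, "unit_variance")
  expect_equal(apply(uv$X[, -3], 2, sd), rep(1, 7), tolerance = 1e-12)
  expect_true(uv$record$zeroVar[3])
  expect_equal(unname(uv$X[, 3]), rep(0, 10))  # centred only
  par <- centerScale(X, "pareto")
  expect_equal(apply(par$X[, -3], 2, sd),
               sqrt(apply(X[, -3], 2, sd)), tolerance = 1e-12)
  expect_error(applyScaling(ctr$record, X[, 1:3]), "mismatch")
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(21)
  X <- matrix(rnorm(60), 12, 5)
  m <- pcaFit(X, nComponents = 5)
  eig <- oracleCovEigen(X)
  # loadings match eigenvectors up to sign
  for (k in 1:5)
    expect_equal(abs(drop(crossprod(pcaLoadings(m)[, k],
                                    eig$vectors[, k]))), 1,
                 tolerance = 1e-8)
  expect_equal(explainedVariance(m), eig$values / sum(eig$values),
               tolerance = 1e-8)
  # orthonormal loadings, non-increasing explained fractions
  expect_equal(crossprod(pcaLoadings(m)), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(explainedVariance(m)) <= 1e-12))
  # full reconstruction returns the centred data
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(scores(m) %*% t(pcaLoadings(m)), Xc, tolerance = 1e-8)
  # rank-1 data: first component carries all variance
  r1 <- pcaFit(outer(1:8, c(2, -1, 3)), nComponents = 2)
  expect_equal(explainedVariance(r1)[1], 1, tolerance = 1e-10)
  expect_error(pcaFit(X[1, , drop = FALSE]), "2 samples")
  expect_error(pcaFit(X, nComponents = 12), "<=")
})

test_that("OPLS fitted responses equal NIPALS PLS1 with k+1 components", {
  set.seed(31)
  for (r in 1:10) {
    n <- sample(10:25, 1); p <- sample(8:30, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("a", "b"), length.out = n)
    yc <- ifelse(y == "a", -1, 1)
    for (k in 0:2) {
      fit <- oplsFit(X, y, nOrth = k)
      expect_equal(scores(fit) * fit@yLoading,
                   oraclePls1(X, yc, k + 1), tolerance = 1e-8)
    }
  }
})

test_that("OPLS orthogonality invariants hold", {
  set.seed(32)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- rep(c("a", "b"), 15)
  fit <- oplsFit(X, y, nOrth = 3)
  tp <- scores(fit)
  for (k in 1:3) {
    to <- fit@orthogonalScores[, k]
    expect_lt(abs(sum(tp * to)) / (sqrt(sum(tp^2)) * sqrt(sum(to^2))),
              1e-6)
  }
  cc <- crossprod(fit@orthogonalScores)
  expect_lt(max(abs(cc[upper.tri(cc)])) / max(diag(cc)), 1e-8)
  expect_error(oplsFit(X, y, nOrth = 40), "large")
  expect_error(oplsFit(X, rep("a", 30), nOrth = 0), "two classes")
})

test_that("purely response-aligned data yield no orthogonal variation and perfect training accuracy", {
  y <- rep(c("a", "b"), each = 6)
  yc <- ifelse(y == "a", -1, 1)
  w <- c(1, -2, 0.5, 3)
  X <- outer(yc, w)
  fit <- oplsFit(X, y, nOrth = 1)
  expect_lt(sum(fit@orthogonalScores^2), 1e-16 * sum(scores(fit)^2) + 1e-20)
  pred <- oplsPredict(fit, X)
  expect_equal(pred$class, y)
})

test_that("OPLS prediction replays training and respects geometry", {
  set.seed(33)
  X <- matrix(rnorm(24 * 10), 24, 10)
  X[13:24, 1:3] <- X[13:24, 1:3] + 3
  y <- rep(c("a", "b"), each = 12)
  fit <- oplsFit(X, y, nOrth = 1)
  pred <- oplsPredict(fit, X)
  expect_equal(pred$response, scores(fit) * fit@yLoading,
               tolerance = 1e-10)
  # a sample at a training class mean is classified into that class
  for (cl in c("a", "b")) {
    mu <- colMeans(X[y == cl, , drop = FALSE])
    expect_equal(oplsPredict(fit, mu)$class, cl)
  }
  # all-zero centred sample: response 0; balanced classes put the
  # threshold at 0, so the tie goes to the +1-coded (second) class
  z <- fit@center
  pz <- oplsPredict(fit, z)
  expect_equal(pz$response, 0, tolerance = 1e-12)
  expect_equal(fit@decisionThreshold, 0)
  expect_equal(pz$class, "b")
  expect_error(oplsPredict(fit, X[, 1:5]), "mismatch")
})

test_that("orthogonal component count selection finds confounders and honours bounds", {
  set.seed(34)
  y <- rep(c("a", "b"), each = 14)
  yc <- ifelse(y == "a", -1, 1)
  # pure single-direction data: nothing orthogonal to remove
  pure <- outer(yc, c(2, -1, 3, 0.5)) + matrix(rnorm(28 * 4, sd = 0.01), 28)
  expect_equal(selectNOrth(pure, y, kMax = 3, seed = 1), 0L)
  expect_equal(selectNOrth(pure, y, kMax = 0, seed = 1), 0L)
  # strong response-orthogonal confounder direction: removing it helps
  conf <- rnorm(28, sd = 20)
  X <- outer(yc, c(1, 0, 0, 0, 0)) * 0.8 +
    outer(conf, c(0.3, 1, -0.5, 0.8, 0.2)) +
    matrix(rnorm(28 * 5, sd = 0.3), 28)
  k <- selectNOrth(X, y, kMax = 3, seed = 1)
  expect_gte(k, 1L)
})

test_that("MCCV is exact on separable data and reproducible", {
  X <- matrix(0, 20, 5)
  X[11:20, 3] <- 10  # disjoint one-bin support
  y <- rep(c("a", "b"), each = 10)
  res <- mccv(X, y, nCycles = 20, seed = 3, kMax = 0)
  expect_equal(meanAccuracy(res), 1)
  cm <- confusionMatrix(res)
  expect_equal(sum(cm[row(cm) != col(cm)]), 0)
  expect_equal(sum(cm), sum(lengths(lapply(res@cycles, `[[`, "test"))))
  # determinism: equal seeds, identical results
  res2 <- mccv(X, y, nCycles = 20, seed = 3, kMax = 0)
  expect_identical(cycleAccuracies(res), cycleAccuracies(res2))
  expect_identical(confusionMatrix(res), confusionMatrix(res2))
  expect_error(mccv(X, rep(c("a", "b"), c(19, 1)), nCycles = 2, seed = 1),
               "at least 2")
})

test_that("different MCCV seeds agree within Monte Carlo error", {
  set.seed(35)
  X <- rbind(matrix(rnorm(15 * 10), 15, 10),
             matrix(rnorm(15 * 10, mean = 0.8), 15, 10))
  y <- rep(c("a", "b"), each = 15)
  r1 <- mccv(X, y, nCycles = 60, seed = 1, kMax = 0)
  r2 <- mccv(X, y, nCycles = 60, seed = 2, kMax = 0)
  se <- sqrt(var(cycleAccuracies(r1)) / 60 + var(cycleAccuracies(r2)) / 60)
  expect_lt(abs(meanAccuracy(r1) - meanAccuracy(r2)), 3 * se + 1e-9)
  # per-cycle mean and pooled aggregation both stored and consistent
  expect_equal(meanAccuracy(r1), mean(cycleAccuracies(r1)))
  expect_equal(r1@pooledAccuracy,
               sum(diag(confusionMatrix(r1))) / sum(confusionMatrix(r1)))
})

test_that("training statistics never leak from held-out samples", {
  set.seed(36)
  X <- rbind(matrix(rnorm(12 * 6), 12, 6),
             matrix(rnorm(12 * 6, mean = 2), 12, 6))
  y <- rep(c("a", "b"), each = 12)
  res <- mccv(X, y, nCycles = 1, seed = 9, kMax = 1)
  test <- res@cycles[[1]]$test
  expect_gte(length(test), 2)
  # poison one held-out sample; the other held-out predictions must not move
  Xp <- X
  Xp[test[1], ] <- 1e6
  resP <- mccv(Xp, y, nCycles = 1, seed = 9, kMax = 1)
  expect_identical(resP@cycles[[1]]$test, test)
  expect_equal(resP@cycles[[1]]$response[-1], res@cycles[[1]]$response[-1],
               tolerance = 1e-10)
})

test_that("PCA misses small discriminating variance that OPLS finds", {
  set.seed(37)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  yc <- ifelse(y == "a", -1, 1)
  p <- 30
  big1 <- rnorm(n, sd = 12); big2 <- rnorm(n, sd = 8)
  dir1 <- rnorm(p); dir1 <- dir1 / sqrt(sum(dir1^2))
  dir2 <- rnorm(p); dir2 <- dir2 - sum(dir2 * dir1) * dir1
  dir2 <- dir2 / sqrt(sum(dir2^2))
  sep <- rnorm(p); sep <- sep - sum(sep * dir1) * dir1 -
    sum(sep * dir2) * dir2
  sep <- sep / sqrt(sum(sep^2))
  X <- outer(big1, dir1) + outer(big2, dir2) + outer(yc, sep) * 1.2 +
    matrix(rnorm(n * p, sd = 0.4), n)
  # discriminating variance below 5 percent of the total
  expect_lt(var(yc * 1.2) / sum(apply(X, 2, var)), 0.05)
  pca <- pcaFit(X, nComponents = 2)
  for (k in 1:2) {
    sc <- scores(pca)[, k]
    between <- summary(lm(sc ~ y))$r.squared
    expect_lt(between, 0.5)
  }
  res <- mccv(X, y, nCycles = 30, seed = 4, kMax = 3)
  expect_gt(meanAccuracy(res), 0.8)
})
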