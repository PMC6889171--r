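test_that("a single predictor saturates in one step at its OLS slope", {
  set.seed(1)
  x <- stdCols(matrix(rnorm(12), 12, 1))
  Y <- 3 * x[, 1] + rnorm(12, 0, 0.1)
  path <- larsPath(x, Y, maxSteps = 1)
  expect_equal(path@sMax, 1L)
  Yc <- Y - mean(Y)
  expect_equal(unname(path@coefficients[1, 1]),
               unname(coef(lm(Yc ~ x[, 1] - 1))[1]), tolerance = 1e-10)
  expect_lt(path@rssTrace[1], sum(Yc^2))
})

test_that("orthonormal designs reproduce the closed-form path", {
  set.seed(2)
  n <- 8; p <- 3
  raw <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  X <- qr.Q(qr(raw))  # orthonormal columns in the centered span
  stopifnot(max(abs(colSums(X))) < 1e-12)
  Y <- rnorm(n, 5, 2)
  cvec <- as.numeric(crossprod(X, Y - mean(Y)))
  path <- larsPath(X, Y, maxSteps = p)
  expect_equal(path@activeOrder, order(-abs(cvec)))
  oracle <- orthoLarsOracle(X, Y)
  for (s in seq_len(p)) {
    got <- path@coefficients[s, seq_len(s)]
    expect_equal(unname(got), unname(oracle[[s]]), tolerance = 1e-8)
  }
})

test_that("active correlations stay tied and dominate inactive ones", {
  set.seed(3)
  n <- 30; p <- 10
  X <- stdCols(matrix(rnorm(n * p), n, p))
  Y <- X[, 2] * 2 - X[, 7] + rnorm(n, 0, 0.5)
  path <- larsPath(X, Y, maxSteps = p)
  Yc <- Y - mean(Y)
  for (s in seq_len(path@sMax)) {
    beta <- numeric(p)
    beta[path@activeOrder[seq_len(path@stepSizes[s])]] <-
      path@coefficients[s, seq_len(path@stepSizes[s])]
    resid <- Yc - X %*% beta
    cc <- abs(as.numeric(crossprod(X, resid)))
    act <- path@activeOrder[seq_len(path@stepSizes[s])]
    if (length(act) > 1) {
      expect_lt(diff(range(cc[act])), 1e-6)
    }
    inact <- setdiff(seq_len(p), act)
    if (length(inact)) {
      expect_lte(max(cc[inact]), max(cc[act]) + 1e-6)
    }
  }
  expect_true(all(diff(path@rssTrace) < 1e-12))
})

test_that("with p < n the full path terminates at the OLS solution", {
  set.seed(4)
  n <- 40; p <- 6
  X <- stdCols(matrix(rnorm(n * p), n, p))
  Y <- rnorm(n, 10, 3)
  path <- larsPath(X, Y, maxSteps = p)
  Yc <- Y - mean(Y)
  ols <- coef(lm(Yc ~ X - 1))
  beta <- numeric(p)
  beta[path@activeOrder] <- path@coefficients[path@sMax, ]
  expect_equal(unname(beta), unname(ols), tolerance = 1e-6)
})

test_that("the Cp statistic follows its defining algebra", {
  expect_equal(cpStatistic(0, 2.5, 199, 198), 197)
  expect_equal(cpStatistic(2.5 * 50, 2.5, 50, 0), 0)
  expect_error(cpStatistic(1, 0, 10, 2), "positive")
  expect_error(cpStatistic(1, 1, 10, 10), "n-1")

  set.seed(5)
  X <- stdCols(matrix(rnorm(25 * 4), 25, 4))
  Y <- rnorm(25)
  path <- larsPath(X, Y, maxSteps = 4)
  recomputed <- vapply(seq_len(path@sMax), function(s) {
    cpStatistic(path@rssTrace[s], path@sigmaBar2, 25, path@stepSizes[s])
  }, 0)
  expect_identical(path@cpTrace, recomputed)
})

test_that("selectVariables returns prefixes of the entry order", {
  set.seed(6)
  X <- stdCols(matrix(rnorm(20 * 5), 20, 5))
  Y <- rnorm(20)
  path <- larsPath(X, Y, maxSteps = 4)
  expect_equal(selectVariables(path, 1),
               which.max(abs(crossprod(X, Y - mean(Y)))),
               ignore_attr = TRUE)
  full <- selectVariables(path)
  expect_false(anyDuplicated(full) > 0)
  expect_lte(length(full), 19)
  expect_error(selectVariables(path, length(full) + 1), "exceeds")
})

test_that("column permutations relabel the path consistently", {
  set.seed(7)
  n <- 25; p <- 8
  X <- stdCols(matrix(rnorm(n * p), n, p))
  Y <- X[, 1] - 2 * X[, 5] + rnorm(n, 0, 0.3)
  perm <- sample(p)
  path1 <- larsPath(X, Y, maxSteps = p)
  path2 <- larsPath(X[, perm], Y, maxSteps = p)
  expect_equal(perm[path2@activeOrder], path1@activeOrder)
  expect_equal(path2@rssTrace, path1@rssTrace, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected or repaired", {
  set.seed(8)
  X <- matrix(rnorm(30), 15, 2)
  expect_error(larsPath(X, rnorm(15)), "centered and unit-norm")

  Xs <- stdCols(matrix(rnorm(15 * 3), 15, 3))
  Xdup <- cbind(Xs, Xs[, 1])  # exact duplicate column
  Y <- Xs[, 1] * 2 + rnorm(15, 0, 0.1)
  expect_warning(path <- larsPath(Xdup, Y, maxSteps = 4), "collinear")
  expect_false(all(c(1, 4) %in% path@activeOrder))
  expect_error(larsPath(Xs, rnorm(15), maxSteps = 15), "n - 1")
})

test_that("the screen stays monotone on a structured-population instance", {
  # moderate-size analogue of the saturated screen: n-1 steps, RSS strictly down
  truth <- simulateReplicate(simConfig(n = 60, p = 500, seed = 31))
  g <- imputeMissing(truth@genotypes)
  K <- computeKinship(g)
  vc <- estimateVarianceComponents(truth@phenotype, K)
  wd <- whiten(truth@phenotype, g, K, vc)
  Yc <- stats::lm.fit(wd@fixedDesign, wd@Y)$residuals
  path <- larsPath(wd@X, Yc, maxSteps = 59)
  expect_lte(length(path@activeOrder), 59)
  expect_true(all(diff(path@rssTrace) < 1e-12))
  expect_equal(path@sMax, 59L)
})
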