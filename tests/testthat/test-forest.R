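makeXy <- function(n = 120, k = 6, seed = 1, signal = TRUE) {
  set.seed(seed)
  X <- matrix(rbinom(n * k, 1, 0.4), n, k)
  colnames(X) <- paste0("v", seq_len(k))
  y <- if (signal) 2 * X[, 1] + rnorm(n, 0, 0.5) else rnorm(n)
  list(X = X, y = y)
}

test_that("a constant response is fitted exactly", {
  d <- makeXy(60, 3, seed = 2)
  fit <- fitForest(d$X, rep(4.2, 60), ntree = 100, seed = 1)
  expect_equal(fit@oobMse, 0)
  expect_true(all(abs(fit@oobPredictions - 4.2) < 1e-12, na.rm = TRUE))
  expect_equal(unname(predict(fit, d$X)), rep(4.2, 60))
})

test_that("refitting with the same seed reproduces OOB results exactly", {
  d <- makeXy(100, 5, seed = 3)
  f1 <- fitForest(d$X, d$y, ntree = 150, seed = 42)
  f2 <- fitForest(d$X, d$y, ntree = 150, seed = 42)
  expect_identical(f1@oobPredictions, f2@oobPredictions)
  expect_identical(f1@oobMse, f2@oobMse)
  f3 <- fitForest(d$X, d$y, ntree = 150, seed = 43)
  expect_false(identical(f1@oobPredictions, f3@oobPredictions))
})

test_that("a noiseless step function is recovered well below the response variance", {
  set.seed(4)
  x <- matrix(rbinom(200, 1, 0.5), 200, 1, dimnames = list(NULL, "v1"))
  y <- ifelse(x[, 1] == 1, 3, -3)
  fit <- fitForest(x, y, ntree = 200, mtry = 1, seed = 5)
  expect_lt(fit@oobMse, var(y) / 4)
})

test_that("mtry is validated and tuned by out-of-bag error", {
  d <- makeXy(100, 6, seed = 6)
  expect_error(fitForest(d$X, d$y, mtry = 7), "mtry")
  expect_error(tuneMtry(d$X, d$y, grid = integer(0)), "nonempty")
  expect_equal(tuneMtry(d$X, d$y, grid = 1L, ntree = 50, seed = 1), 1L)
  x1 <- d$X[, 1, drop = FALSE]
  expect_equal(tuneMtry(x1, d$y, ntree = 50, seed = 1), 1L)

  grid <- c(1L, 3L, 6L)
  best <- tuneMtry(d$X, d$y, grid = grid, ntree = 100, seed = 9)
  oob <- vapply(grid, function(m) {
    fitForest(d$X, d$y, ntree = 100, mtry = m, seed = 9)@oobMse
  }, 0)
  expect_equal(best, grid[which.min(oob)])
})

test_that("null variables score near zero and the true predictor separates", {
  nulls <- vapply(1:50, function(r) {
    d <- makeXy(60, 4, seed = 100 + r, signal = TRUE)
    fit <- fitForest(d$X, d$y, ntree = 100, mtry = 2, seed = r)
    imp <- permutationImportance(fit, d$X, d$y, seed = fit@seed)
    mean(imp@scores[c("v2", "v3", "v4")])
  }, 0)
  expect_lt(abs(mean(nulls)), 0.5)

  set.seed(7)
  X <- matrix(rbinom(300 * 5, 1, 0.5), 300, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- 4 * X[, 3]  # noiseless, sole predictor
  fit <- fitForest(X, y, ntree = 200, mtry = 2, seed = 8)
  imp <- permutationImportance(fit, X, y, seed = fit@seed)
  expect_gt(imp@scores["v3"], 0)
  expect_true(all(imp@scores["v3"] > imp@scores[c("v1", "v2", "v4", "v5")]))
})

test_that("importance is stable under variable relabeling", {
  d <- makeXy(120, 5, seed = 9)
  fit <- fitForest(d$X, d$y, ntree = 200, mtry = 2, seed = 11)
  imp <- permutationImportance(fit, d$X, d$y, seed = 11)
  perm <- c(3, 1, 5, 2, 4)
  Xp <- d$X[, perm]
  fitP <- fitForest(Xp, d$y, ntree = 200, mtry = 2, seed = 11)
  impP <- permutationImportance(fitP, Xp, d$y, seed = 11)
  # same seed, same data up to column labels: scores agree by name
  expect_equal(sort(names(imp@scores)), sort(names(impP@scores)))
  expect_equal(cor(imp@scores[paste0("v", 1:5)], impP@scores[paste0("v", 1:5)]),
               1, tolerance = 0.25)
})

test_that("permuting the response inflates the out-of-bag error", {
  d <- makeXy(150, 4, seed = 10)
  fit <- fitForest(d$X, d$y, ntree = 150, seed = 12)
  set.seed(13)
  fitPerm <- fitForest(d$X, sample(d$y), ntree = 150, seed = 12)
  expect_gt(fitPerm@oobMse, fit@oobMse)
})

test_that("scores agree with the classical %IncMSE implementation", {
  # independent cross-check against randomForest on the same data
  set.seed(14)
  n <- 150; k <- 8
  X <- matrix(rbinom(n * k, 1, 0.3), n, k,
              dimnames = list(NULL, paste0("v", 1:k)))
  y <- 2.5 * X[, 1] + 1.5 * X[, 4] + rnorm(n)
  fit <- fitForest(X, y, ntree = 500, mtry = 3, seed = 15)
  imp <- permutationImportance(fit, X, y, seed = 15)
  rf <- randomForest::randomForest(X, y, ntree = 500, mtry = 3,
                                   importance = TRUE)
  ref <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  expect_gt(cor(imp@scores[names(ref)], ref), 0.8)
  expect_equal(order(-imp@scores)[1:2], order(-ref)[1:2])
})

test_that("multiple permutation draws average toward the single-draw score", {
  d <- makeXy(100, 4, seed = 16)
  fit <- fitForest(d$X, d$y, ntree = 200, mtry = 2, seed = 17)
  one <- permutationImportance(fit, d$X, d$y, permutations = 1, seed = 17)
  many <- permutationImportance(fit, d$X, d$y, permutations = 4, seed = 17)
  expect_equal(many@permutations, 4L)
  expect_equal(unname(many@scores["v1"]), unname(one@scores["v1"]),
               tolerance = 0.5)
})
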