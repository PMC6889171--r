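#' Mean absolute error
#'
#' `MAE = (1/n) sum |y_i - yhat_i|`.
#'
#' @param y observed values.
#' @param yhat predicted values (same length).
#' @return the mean absolute error.
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (!length(y)) stop("empty input")
  if (anyNA(y) || anyNA(yhat)) stop("missing values not allowed")
  mean(abs(y - yhat))
}

#' Mean absolute percentage error (fraction scale)
#'
#' `MAPE = (1/n) sum |(y_i - yhat_i) / y_i|`. Reported on the fraction
#' scale (no x100). Undefined when any observed value is zero.
#'
#' @inheritParams mae
#' @return the mean absolute percentage error.
#' @export
mape <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (!length(y)) stop("empty input")
  if (anyNA(y) || anyNA(yhat)) stop("missing values not allowed")
  zero <- which(y == 0)
  if (length(zero)) {
    stop("MAPE undefined: observed value is zero at index ", zero[1])
  }
  mean(abs((y - yhat) / y))
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation with `n - 1` denominators:
#' the sum of `((y_i - ybar)/s_y) * ((yhat_i - yhatbar)/s_yhat)` divided by
#' `n - 1`, so that the result is bounded by 1 in absolute value.
#'
#' @inheritParams mae
#' @return the correlation in `[-1, 1]`.
#' @export
pearsonR <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2) stop("need at least 2 observations")
  if (anyNA(y) || anyNA(yhat)) stop("missing values not allowed")
  sy <- stats::sd(y)
  syh <- stats::sd(yhat)
  if (sy == 0 || syh == 0) stop("correlation undefined for constant input")
  n <- length(y)
  r <- sum(((y - mean(y)) / sy) * ((yhat - mean(yhat)) / syh)) / (n - 1)
  stopifnot(abs(r) <= 1 + 1e-9)
  min(1, max(-1, r))
}

#' Seeded ten-fold cross-validation of a pipeline method
#'
#' Samples are partitioned at random into `folds` folds of near-equal size
#' (differing by at most one). For each fold the full method pipeline --
#' including MAF filtering, kinship, REML, whitening and LARS screening for
#' `"tslrf"` -- is re-run on the training samples only; the held-out
#' samples are predicted by that fold's forest. Accuracy metrics are
#' computed on the pooled out-of-fold predictions, so no information from a
#' test fold can reach its training stage.
#'
#' @param g a [GenotypeMatrix-class].
#' @param y named numeric phenotype.
#' @param cfg a [tslrfConfig()].
#' @param method `"tslrf"`, `"rf"` or `"tsrf"`.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param groupSize TSRF comparator group size.
#' @return a [CVResult-class].
#' @export
tenFoldCv <- function(g, y, cfg = tslrfConfig(), method = c("tslrf", "rf", "tsrf"),
                      folds = 10L, seed = 1L, groupSize = 1000L) {
  method <- match.arg(method)
  al <- alignSamples(g, y)
  g <- al$g
  y <- al$y
  n <- length(y)
  if (n < 20) stop("need at least 20 samples")
  set.seed(deriveSeed(seed, "folds"))
  fold <- sample(rep(seq_len(folds), length.out = n))
  if (min(table(fold)) < 2) stop("a fold has fewer than 2 samples")
  pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    stageLog("cv", "fold %d/%d (%s)", f, folds, method)
    trainIdx <- which(fold != f)
    testIdx <- which(fold == f)
    gTrain <- g[trainIdx, ]
    gTest <- g[testIdx, ]
    yTrain <- y[trainIdx]
    pc <- cfg
    pc$seed <- deriveSeed(seed, paste0("fold", f))
    if (method == "tslrf") {
      fit <- runTslrf(gTrain, yTrain, pc)
      pred[testIdx] <- predict(fit, gTest)
    } else if (method == "rf") {
      fit <- rfBaselineForest(gTrain, yTrain, pc)
      gT <- imputeMissing(gTest[, fit$markers], strategy = fit$strategy)
      pred[testIdx] <- predict(fit$forest, genotypes(gT))
    } else {
      tab <- importanceTable(
        runTsrfComparator(gTrain, yTrain, pc, groupSize = groupSize))
      keep <- intersect(markerIds(gTrain), tab$marker_id[!is.na(tab$score)])
      gTr <- imputeMissing(gTrain[, keep], strategy = pc$imputeStrategy)
      forest <- fitForest(genotypes(gTr), yTrain, ntree = pc$ntree,
                          seed = deriveSeed(pc$seed, "tsrf-final"))
      gT <- imputeMissing(gTest[, keep], strategy = pc$imputeStrategy)
      pred[testIdx] <- predict(forest, genotypes(gT))
    }
  }
  new("CVResult", foldAssignment = as.integer(fold), predictions = pred,
      observed = as.numeric(y), mae = mae(y, pred), mape = mape(y, pred),
      pearsonR = pearsonR(y, pred), method = method, seed = as.integer(seed))
}

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s, %d folds): MAE %.4f, MAPE %.4f, r %.4f\n",
              object@method, length(unique(object@foldAssignment)),
              object@mae, object@mape, object@pearsonR))
})
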