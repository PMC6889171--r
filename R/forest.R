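#' Fit a bagged regression forest
#'
#' Ensemble of CART-style regression trees, each grown on a bootstrap
#' resample with `mtry` candidate variables drawn at every node; the
#' regression prediction is the average over trees. Out-of-bag (OOB)
#' predictions and OOB mean squared error are retained. The tree-growing
#' controls mirror the classical regression defaults: no depth limit,
#' minimum node size 5. Fitting is delegated to \pkg{ranger} (single
#' thread), so the same seed reproduces the fit exactly.
#'
#' @param X numeric matrix of predictors (column names required; assigned
#'   `v1..vk` when absent).
#' @param Y numeric response.
#' @param ntree number of trees (default 500).
#' @param mtry per-node candidate-variable count; default
#'   `max(floor(k/3), 1)`, the classical regression forest default.
#' @param seed integer seed threaded through the bootstrap draws.
#' @return a [ForestModel-class].
#' @export
fitForest <- function(X, Y, ntree = 500L, mtry = NULL, seed = 1L) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 1) stop("at least one predictor is required")
  if (ntree < 1) stop("ntree must be at least 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(k))
  if (is.null(mtry)) mtry <- max(1L, floor(k / 3))
  if (mtry > k) stop("mtry must not exceed the number of predictors")
  fit <- ranger::ranger(x = X, y = as.numeric(Y), num.trees = ntree,
                        mtry = mtry, min.node.size = 5,
                        num.threads = 1, seed = seed, verbose = FALSE)
  oob <- fit$predictions
  oobMse <- mean((oob - Y)^2, na.rm = TRUE)
  new("ForestModel", fit = fit, ntree = as.integer(ntree),
      mtry = as.integer(mtry), oobPredictions = as.numeric(oob),
      oobMse = oobMse, seed = as.integer(seed),
      variableNames = colnames(X))
}

setMethod("show", "ForestModel", function(object) {
  cat(sprintf("ForestModel: %d trees, mtry %d over %d variables, OOB MSE %.4g\n",
              object@ntree, object@mtry, length(object@variableNames),
              object@oobMse))
})

#' Predict from a fitted ForestModel
#'
#' @param object a [ForestModel-class].
#' @param newdata matrix covering the model's variables (by column name).
#' @param ... ignored.
#' @return numeric predictions.
#' @export
setMethod("predict", "ForestModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) colnames(newdata) <- object@variableNames
  miss <- setdiff(object@variableNames, colnames(newdata))
  if (length(miss)) stop("newdata lacks variables: ", paste(miss, collapse = ", "))
  stats::predict(object@fit,
                 data = newdata[, object@variableNames, drop = FALSE],
                 num.threads = 1)$predictions
})

#' Choose mtry by out-of-bag error
#'
#' Fits one forest per grid value (same seed, so the bootstrap draws are
#' paired) and returns the value minimizing OOB mean squared error; ties go
#' to the smallest mtry.
#'
#' @param X,Y training data as in [fitForest()].
#' @param grid candidate mtry values, each in `[1, k]`; default
#'   `{floor(k/3), floor(sqrt(k)), floor(k/2), k}` with duplicates removed.
#' @param ntree trees per candidate fit.
#' @param seed integer seed.
#' @return the selected mtry (integer).
#' @export
tuneMtry <- function(X, Y, grid = NULL, ntree = 500L, seed = 1L) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (is.null(grid)) {
    grid <- unique(pmax(1L, c(floor(k / 3), floor(sqrt(k)), floor(k / 2), k)))
  }
  if (!length(grid)) stop("mtry grid must be nonempty")
  if (any(grid < 1 | grid > k)) stop("mtry grid values must lie in [1, k]")
  grid <- as.integer(sort(grid))
  err <- vapply(grid, function(m) {
    fitForest(X, Y, ntree = ntree, mtry = m, seed = seed)@oobMse
  }, 0)
  grid[which.min(err)]  # sorted grid => ties resolve to the smallest mtry
}

#' Permutation importance (%IncMSE) of a fitted forest
#'
#' For every tree and variable, the variable's values are permuted among the
#' tree's out-of-bag samples and the increase in OOB mean squared error is
#' recorded; the per-variable score is the mean increase across trees
#' divided by its standard error (the scaled %IncMSE convention) or the raw
#' mean increase when `scaled = FALSE`. With `permutations > 1` the score is
#' averaged over that many independent forest-and-permutation realizations
#' seeded from `seed`.
#'
#' @param model a [ForestModel-class].
#' @param X,Y the training data the model was fitted on.
#' @param permutations independent permutation draws to average (default 1).
#' @param seed integer seed for the permutation draws.
#' @param scaled divide the mean MSE increase by its standard error
#'   (default TRUE).
#' @return an [ImportanceResult-class] with one score per model variable.
#' @export
permutationImportance <- function(model, X, Y, permutations = 1L,
                                  seed = model@seed, scaled = TRUE) {
  stopifnot(is(model, "ForestModel"))
  if (permutations < 1) stop("permutations must be at least 1")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- model@variableNames
  acc <- NULL
  for (b in seq_len(permutations)) {
    fit <- ranger::ranger(x = X[, model@variableNames, drop = FALSE],
                          y = as.numeric(Y),
                          num.trees = model@ntree, mtry = model@mtry,
                          min.node.size = 5, num.threads = 1,
                          importance = "permutation", verbose = FALSE,
                          scale.permutation.importance = scaled,
                          seed = if (b == 1L) seed else deriveSeed(seed, paste0("perm", b)))
    sc <- fit$variable.importance
    acc <- if (is.null(acc)) sc else acc + sc
  }
  scores <- acc / permutations
  covered <- variableOobCoverage(model)
  if (any(!covered)) {
    warning(sprintf("%d variable(s) had no OOB coverage; scores set to NA",
                    sum(!covered)))
    scores[!covered] <- NA_real_
  }
  new("ImportanceResult", scores = scores,
      permutations = as.integer(permutations), seed = as.integer(seed),
      scaled = scaled)
}

# a variable has OOB coverage unless every sample was in-bag in every tree;
# with a bootstrap of size n this is essentially always TRUE, but degenerate
# single-tree fits can violate it
variableOobCoverage <- function(model) {
  anyOob <- any(!is.nan(model@oobPredictions))
  stats::setNames(rep(anyOob, length(model@variableNames)),
                  model@variableNames)
}
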