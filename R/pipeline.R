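#' Pipeline configuration
#'
#' Bundles the tunable parameters of the two-stage pipeline and its
#' comparators.
#'
#' @param mafThreshold minor-allele-frequency filter (default 0.10).
#' @param larsMaxSteps maximum LARS steps; `NULL` means `n - 1`.
#' @param ntree trees per forest (default 500).
#' @param mtryGrid candidate mtry values for OOB tuning; `NULL` means
#'   `{floor(k/3), floor(sqrt(k)), floor(k/2), k}`.
#' @param topM report size for [topMarkers()] views (default 20).
#' @param seed master seed; all stage seeds are derived from it.
#' @param imputeStrategy missing-call imputation, see [imputeMissing()].
#' @param covariates optional numeric matrix of extra fixed-effect columns
#'   (population-structure axes), rows named by sample id.
#' @param kinship optional precomputed [KinshipMatrix-class]; computed from
#'   the filtered genotypes when `NULL`.
#' @param permutations permutation draws for the importance stage.
#' @param scaledImportance use the scaled %IncMSE convention (default TRUE).
#' @return a named list of class `tslrfConfig`.
#' @export
tslrfConfig <- function(mafThreshold = 0.10, larsMaxSteps = NULL,
                        ntree = 500L, mtryGrid = NULL, topM = 20L,
                        seed = 1L, imputeStrategy = "column_mean",
                        covariates = NULL, kinship = NULL,
                        permutations = 1L, scaledImportance = TRUE) {
  stopifnot(mafThreshold >= 0, mafThreshold <= 0.5, ntree >= 1, topM >= 1)
  structure(list(mafThreshold = mafThreshold, larsMaxSteps = larsMaxSteps,
                 ntree = as.integer(ntree), mtryGrid = mtryGrid,
                 topM = as.integer(topM), seed = as.integer(seed),
                 imputeStrategy = imputeStrategy, covariates = covariates,
                 kinship = kinship, permutations = as.integer(permutations),
                 scaledImportance = scaledImportance),
            class = "tslrfConfig")
}

alignSamples <- function(g, y) {
  ids <- intersect(sampleIds(g), names(y))
  if (!length(ids)) stop("no samples shared between genotypes and phenotype")
  y <- y[ids]
  keep <- !is.na(y)
  ids <- ids[keep]
  list(g = g[match(ids, sampleIds(g)), ], y = y[keep])
}

prepareGenotypes <- function(g, cfg) {
  g <- filterMaf(g, cfg$mafThreshold)
  if (nMarkers(g) < 2) stop("fewer than 2 polymorphic markers after MAF filtering")
  imputeMissing(g, cfg$imputeStrategy)
}

fixedDesignFor <- function(cfg, ids) {
  W <- matrix(1, length(ids), 1)
  if (!is.null(cfg$covariates)) {
    cov <- as.matrix(cfg$covariates)
    if (!is.null(rownames(cov))) cov <- cov[ids, , drop = FALSE]
    W <- cbind(W, cov)
  }
  W
}

#' Run the two-stage pipeline
#'
#' Stage sequence: MAF filter, imputation, kinship, REML variance
#' components, whitening, LARS screen to at most `n - 1` SNPs, mtry-tuned
#' random forest on the screened subset, permutation importance (%IncMSE)
#' and ranking. Samples are matched between genotypes and phenotype by id.
#'
#' @param g a [GenotypeMatrix-class].
#' @param y named numeric phenotype vector.
#' @param cfg a [tslrfConfig()] list.
#' @return a [TslrfResult-class]; `importanceTable(result)` holds the ranked
#'   scores of the LARS-selected SNPs (markers not selected carry no score).
#' @export
runTslrf <- function(g, y, cfg = tslrfConfig()) {
  al <- alignSamples(g, y)
  g <- al$g
  y <- al$y
  n <- nSamples(g)
  if (n < 20) stop("need at least 20 samples")
  g <- prepareGenotypes(g, cfg)
  stageLog("filter", "%d samples x %d markers after MAF >= %.2f",
           nSamples(g), nMarkers(g), cfg$mafThreshold)
  W <- fixedDesignFor(cfg, sampleIds(g))
  k <- if (is.null(cfg$kinship)) computeKinship(g) else cfg$kinship
  stageLog("kinship", "%d x %d relatedness matrix", n, n)
  vc <- estimateVarianceComponents(y, k, fixedDesign = W)
  stageLog("reml", "lambda-hat %.4g, sigma2-hat %.4g", vc@lambda, vc@sigma2)
  wd <- whiten(y, g, k, vc, fixedDesign = W)
  stageLog("whiten", "%d standardized columns (%d dropped)",
           ncol(wd@X), length(wd@dropped))
  # project the transformed fixed effects out of Y before screening
  Yc <- stats::lm.fit(wd@fixedDesign, wd@Y)$residuals
  maxSteps <- if (is.null(cfg$larsMaxSteps)) n - 1L else min(cfg$larsMaxSteps, n - 1L)
  lp <- larsPath(wd@X, Yc, maxSteps = min(maxSteps, ncol(wd@X)))
  stageLog("lars", "%d steps, %d variables screened", lp@sMax,
           length(lp@activeOrder))
  selIdx <- selectVariables(lp)
  selIds <- colnames(wd@X)[selIdx]
  Xsel <- wd@X[, selIdx, drop = FALSE]
  seeds <- c(forest = deriveSeed(cfg$seed, "forest"),
             tune = deriveSeed(cfg$seed, "tune"),
             predict = deriveSeed(cfg$seed, "predict"))
  mtry <- tuneMtry(Xsel, wd@Y, grid = cfg$mtryGrid, ntree = cfg$ntree,
                   seed = seeds[["tune"]])
  forest <- fitForest(Xsel, wd@Y, ntree = cfg$ntree, mtry = mtry,
                      seed = seeds[["forest"]])
  stageLog("forest", "%d trees, tuned mtry %d, OOB MSE %.4g",
           forest@ntree, forest@mtry, forest@oobMse)
  imp <- permutationImportance(forest, Xsel, wd@Y,
                               permutations = cfg$permutations,
                               seed = seeds[["forest"]],
                               scaled = cfg$scaledImportance)
  stageLog("importance", "scores for %d screened SNPs", length(imp@scores))
  tab <- makeImportanceTable(imp@scores, markerInfo(g))
  # companion forest on the observed scale: predictions must not inherit
  # the sample-space whitening scale (C does not extend to new samples)
  Zsel <- genotypes(g)[, selIds, drop = FALSE]
  predCenters <- colMeans(Zsel)
  Zc <- sweep(Zsel, 2, predCenters)
  predScales <- pmax(sqrt(colSums(Zc^2)), 1e-12)
  Xpred <- sweep(Zc, 2, predScales, "/")
  predForest <- fitForest(Xpred, y, ntree = cfg$ntree, mtry = mtry,
                          seed = seeds[["predict"]])
  new("TslrfResult", importance = tab, larsPath = lp,
      varianceComponents = vc, forest = forest,
      predictionForest = predForest, predCenters = predCenters,
      predScales = predScales, whitened = wd,
      selected = selIds, config = unclass(cfg), seeds = seeds)
}

setMethod("show", "TslrfResult", function(object) {
  cat("TslrfResult\n")
  cat(sprintf("  lambda-hat %.4g, sigma2-hat %.4g\n",
              object@varianceComponents@lambda,
              object@varianceComponents@sigma2))
  cat(sprintf("  %d SNPs screened by LARS; forest mtry %d, %d trees\n",
              length(object@selected), object@forest@mtry,
              object@forest@ntree))
  cat("  top of the importance ranking:\n")
  print(utils::head(object@importance@table, 5))
})

#' Predict phenotypes from a fitted TslrfResult
#'
#' New samples are mapped onto the training feature scale by standardizing
#' their raw genotype codes at the selected markers with the training
#' column centers and scales, and fed to the observed-scale companion
#' forest (the sample-space whitening transform only exists for the
#' training set, so predictions are made on the observed phenotype scale).
#'
#' @param object a [TslrfResult-class].
#' @param newdata a [GenotypeMatrix-class] containing the selected markers.
#' @param ... ignored.
#' @return named numeric predictions.
#' @export
setMethod("predict", "TslrfResult", function(object, newdata, ...) {
  stopifnot(is(newdata, "GenotypeMatrix"))
  idx <- match(object@selected, markerIds(newdata))
  if (anyNA(idx)) stop("newdata lacks selected markers")
  g <- imputeMissing(newdata[, sort(idx)],
                     strategy = object@config$imputeStrategy)
  Z <- genotypes(g)
  ctr <- object@predCenters[colnames(Z)]
  scl <- object@predScales[colnames(Z)]
  Xnew <- sweep(sweep(Z, 2, ctr), 2, scl, "/")
  p <- predict(object@predictionForest, Xnew)
  stats::setNames(p, sampleIds(g))
})

#' Single-stage random-forest baseline
#'
#' One mtry-default regression forest on all MAF-filtered SNPs (no
#' whitening, no screening) with %IncMSE scores for every SNP.
#'
#' @inheritParams runTslrf
#' @return an [ImportanceTable-class] covering all filtered SNPs.
#' @export
runRfBaseline <- function(g, y, cfg = tslrfConfig()) {
  al <- alignSamples(g, y)
  g <- prepareGenotypes(al$g, cfg)
  y <- al$y
  X <- genotypes(g)
  forest <- fitForest(X, y, ntree = cfg$ntree,
                      seed = deriveSeed(cfg$seed, "rf-baseline"))
  imp <- permutationImportance(forest, X, y,
                               permutations = cfg$permutations,
                               seed = forest@seed,
                               scaled = cfg$scaledImportance)
  makeImportanceTable(imp@scores, markerInfo(g))
}

# baseline forest without importance, for cross-validation prediction
rfBaselineForest <- function(g, y, cfg) {
  al <- alignSamples(g, y)
  g <- prepareGenotypes(al$g, cfg)
  forest <- fitForest(genotypes(g), al$y, ntree = cfg$ntree,
                      seed = deriveSeed(cfg$seed, "rf-baseline"))
  list(forest = forest, markers = markerIds(g),
       strategy = cfg$imputeStrategy)
}

#' Iterative-elimination comparator (grouped backward screening)
#'
#' Approximate reconstruction of the two-stage stepwise forest comparator:
#' SNPs are taken in consecutive positional groups of `groupSize`; a forest
#' with permutation importance is fitted on the surviving set and the
#' `groupSize` lowest-scoring variables are removed, repeating until at most
#' `groupSize` survive. The final forest supplies the survivors' scores.
#'
#' @inheritParams runTslrf
#' @param groupSize variables removed per round (default 1000).
#' @return an [ImportanceTable-class] over the surviving SNPs.
#' @export
runTsrfComparator <- function(g, y, cfg = tslrfConfig(), groupSize = 1000L) {
  al <- alignSamples(g, y)
  g <- prepareGenotypes(al$g, cfg)
  y <- al$y
  if (groupSize >= nMarkers(g)) {
    warning("groupSize >= marker count; falling back to the single-stage forest")
    return(runRfBaseline(g, y, cfg))
  }
  surviving <- markerIds(g)
  round <- 0L
  repeat {
    round <- round + 1L
    X <- genotypes(g)[, surviving, drop = FALSE]
    forest <- fitForest(X, y, ntree = cfg$ntree,
                        seed = deriveSeed(cfg$seed, paste0("tsrf", round)))
    imp <- permutationImportance(forest, X, y, seed = forest@seed,
                                 scaled = cfg$scaledImportance)
    if (length(surviving) <= groupSize) {
      return(makeImportanceTable(imp@scores, markerInfo(g)))
    }
    drop <- names(sort(imp@scores, na.last = FALSE))[seq_len(groupSize)]
    surviving <- setdiff(surviving, drop)
  }
}
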