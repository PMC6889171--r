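#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GenotypeMatrix: coded marker genotypes with marker metadata
#'
#' Samples are rows, markers are columns. Genotypes are coded as minor-allele
#' counts: `{0,1}` for inbred (fully homozygous) panels, `{0,1,2}` for
#' heterozygote-capable material. The `codeMax` slot records the maximum code
#' (the per-sample allele dosage ceiling), which is also the denominator unit
#' used for allele-frequency computations. Positions are 1-based bp.
#'
#' @slot genotypes numeric matrix, n samples x p markers, dimnames set to
#'   sample ids and marker ids.
#' @slot markers data.frame with one row per marker: `id`, `chrom`, `pos`.
#' @slot missing logical matrix marking missing calls (same shape as
#'   `genotypes`).
#' @slot codeMax integer(1), 1 for inbred coding, 2 for dosage coding.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(
    genotypes = "matrix",
    markers = "data.frame",
    missing = "matrix",
    codeMax = "integer"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  g <- object@genotypes
  mk <- object@markers
  if (!is.numeric(g)) msg <- c(msg, "genotypes must be numeric")
  if (nrow(mk) != ncol(g)) {
    msg <- c(msg, "marker metadata rows must equal genotype columns")
  }
  if (!all(c("id", "chrom", "pos") %in% names(mk))) {
    msg <- c(msg, "markers must have columns id, chrom, pos")
  }
  if (!identical(dim(object@missing), dim(g))) {
    msg <- c(msg, "missing mask must match genotype dimensions")
  }
  if (is.null(rownames(g))) msg <- c(msg, "genotypes must carry sample ids as rownames")
  if (!(object@codeMax %in% c(1L, 2L))) msg <- c(msg, "codeMax must be 1 or 2")
  if (nrow(mk) > 0 && length(msg) == 0L) {
    if (any(mk$pos < 0, na.rm = TRUE)) msg <- c(msg, "positions must be non-negative")
    ord <- unlist(lapply(split(mk$pos, factor(mk$chrom, levels = unique(mk$chrom))),
                         function(p) is.unsorted(p, na.rm = TRUE)), use.names = FALSE)
    if (any(ord)) msg <- c(msg, "positions must be non-decreasing within a chromosome")
    obs <- g[!object@missing]
    # mean-imputed calls are fractional, so the check is a range, not a set
    if (length(obs) && (min(obs) < 0 || max(obs) > object@codeMax)) {
      msg <- c(msg, sprintf("non-missing genotype codes must lie in [0, %d]", object@codeMax))
    }
  }
  if (length(msg)) msg else TRUE
})

#' KinshipMatrix: symmetric positive semidefinite relatedness matrix
#'
#' @slot values n x n numeric matrix with sample ids as dimnames.
#' @exportClass KinshipMatrix
setClass("KinshipMatrix", representation(values = "matrix"))

setValidity("KinshipMatrix", function(object) {
  K <- object@values
  if (nrow(K) != ncol(K)) return("kinship matrix must be square")
  if (max(abs(K - t(K))) > 1e-8) return("kinship matrix must be symmetric (tol 1e-8)")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    return("kinship matrix must be positive semidefinite")
  }
  TRUE
})

#' VarianceComponents: REML estimates of the polygenic null model
#'
#' Null mixed model y = W alpha + u + e with u ~ MVN(0, sigmaG2 * K) and
#' e ~ MVN(0, sigma2 * I); lambda = sigmaG2 / sigma2.
#'
#' @slot sigmaG2 polygenic variance (>= 0).
#' @slot sigma2 residual variance (> 0).
#' @slot lambda variance ratio sigmaG2 / sigma2.
#' @slot remlLogLik restricted log-likelihood at the optimum.
#' @slot boundary TRUE when lambda was unidentifiable and pinned to a bound.
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(
    sigmaG2 = "numeric",
    sigma2 = "numeric",
    lambda = "numeric",
    remlLogLik = "numeric",
    boundary = "logical"
  )
)

setValidity("VarianceComponents", function(object) {
  if (object@sigma2 <= 0) return("sigma2 must be positive")
  if (object@sigmaG2 < 0) return("sigmaG2 must be non-negative")
  if (!is.finite(object@remlLogLik)) return("remlLogLik must be finite")
  rel <- abs(object@lambda - object@sigmaG2 / object@sigma2) /
    max(1e-12, abs(object@lambda))
  if (rel > 1e-6) return("lambda must equal sigmaG2/sigma2 (rel tol 1e-6)")
  TRUE
})

#' WhitenedData: transformed phenotype and standardized marker matrix
#'
#' Holds Y = C y and the transformed marker matrix X with every retained
#' column centered (sum 0) and unit-norm (sum of squares 1), where
#' C = (lambda K + I)^(-1/2). Column centers/scales are kept so that new
#' samples can be mapped onto the training feature scale.
#'
#' @slot Y length-n transformed phenotype.
#' @slot X n x p' standardized transformed marker matrix.
#' @slot transform the n x n symmetric positive definite whitening matrix.
#' @slot fixedDesign transformed fixed-effect design (intercept at minimum).
#' @slot centers,scales per-column standardization constants of `X`.
#' @slot dropped marker ids whose transformed column was constant.
#' @exportClass WhitenedData
setClass("WhitenedData",
  representation(
    Y = "numeric",
    X = "matrix",
    transform = "matrix",
    fixedDesign = "matrix",
    centers = "numeric",
    scales = "numeric",
    dropped = "character"
  )
)

setValidity("WhitenedData", function(object) {
  X <- object@X
  if (ncol(X)) {
    cs <- colSums(X)
    ss <- colSums(X^2)
    if (max(abs(cs)) > 1e-8) return("columns of X must sum to zero (tol 1e-8)")
    if (max(abs(ss - 1)) > 1e-8) return("columns of X must have unit sum of squares (tol 1e-8)")
  }
  if (length(object@Y) != nrow(X)) return("Y length must match rows of X")
  TRUE
})

#' LarsPath: Least Angle Regression path over a standardized design
#'
#' @slot activeOrder marker column indices in order of entry.
#' @slot coefficients sMax x length(activeOrder) matrix; row s holds the
#'   coefficients (on the standardized scale) after step s, columns in
#'   `activeOrder` order.
#' @slot rssTrace per-step residual sum of squares.
#' @slot cpTrace per-step Cp-type risk estimate.
#' @slot sMax number of steps performed.
#' @slot sigmaBar2 residual-variance estimate used in the Cp trace.
#' @slot markerIds optional marker ids for the design columns.
#' @exportClass LarsPath
setClass("LarsPath",
  representation(
    activeOrder = "integer",
    coefficients = "matrix",
    rssTrace = "numeric",
    cpTrace = "numeric",
    sMax = "integer",
    stepSizes = "integer",
    sigmaBar2 = "numeric",
    markerIds = "character"
  )
)

setValidity("LarsPath", function(object) {
  if (object@sMax != length(object@rssTrace)) return("rssTrace length must equal sMax")
  if (length(object@cpTrace) != object@sMax) return("cpTrace length must equal sMax")
  if (anyDuplicated(object@activeOrder)) return("active set indices must be unique")
  TRUE
})

#' ForestModel: bagged regression-tree ensemble with OOB diagnostics
#'
#' Thin S4 wrapper around a fitted \pkg{ranger} regression forest, keeping
#' the out-of-bag predictions, OOB mean squared error and the fit parameters
#' needed to reproduce it.
#'
#' @slot fit the underlying ranger object.
#' @slot ntree number of trees.
#' @slot mtry per-node candidate-variable count.
#' @slot oobPredictions length-n OOB predictions (NaN where a sample was
#'   never out-of-bag).
#' @slot oobMse out-of-bag mean squared error.
#' @slot seed integer seed used for the fit.
#' @slot variableNames column names of the training matrix.
#' @exportClass ForestModel
setClass("ForestModel",
  representation(
    fit = "ANY",
    ntree = "integer",
    mtry = "integer",
    oobPredictions = "numeric",
    oobMse = "numeric",
    seed = "integer",
    variableNames = "character"
  )
)

#' ImportanceResult: permutation importance scores for a fitted forest
#'
#' @slot scores named per-variable %IncMSE scores.
#' @slot permutations number of independent permutation draws averaged.
#' @slot seed integer seed.
#' @slot scaled TRUE for the mean/SE (%IncMSE) convention, FALSE for the raw
#'   mean OOB MSE increase.
#' @exportClass ImportanceResult
setClass("ImportanceResult",
  representation(
    scores = "numeric",
    permutations = "integer",
    seed = "integer",
    scaled = "logical"
  )
)

#' ImportanceTable: ranked per-SNP importance scores
#'
#' @slot table data.frame with columns marker_id, chromosome, position,
#'   score, rank (rank 1 = largest score; ties broken by marker order).
#' @exportClass ImportanceTable
setClass("ImportanceTable", representation(table = "data.frame"))

setValidity("ImportanceTable", function(object) {
  tb <- object@table
  need <- c("marker_id", "chromosome", "position", "score", "rank")
  if (!all(need %in% names(tb))) {
    return(paste("table must have columns", paste(need, collapse = ", ")))
  }
  scored <- tb[!is.na(tb$score), , drop = FALSE]
  if (nrow(scored)) {
    if (!setequal(scored$rank, seq_len(nrow(scored)))) {
      return("ranks of scored markers must be a permutation of 1..k")
    }
    sc <- scored$score[order(scored$rank)]
    if (is.unsorted(rev(sc), strictly = FALSE)) return("scores must be non-increasing in rank")
  }
  if (any(is.na(tb$score) & !is.na(tb$rank))) {
    return("unscored markers must have NA rank")
  }
  TRUE
})

#' TslrfResult: full output of the two-stage pipeline
#'
#' @slot importance ImportanceTable over the LARS-selected SNPs.
#' @slot larsPath the stage-1 LarsPath.
#' @slot varianceComponents REML VarianceComponents of the null model.
#' @slot forest the fitted stage-2 ForestModel (whitened scale; importance).
#' @slot predictionForest companion ForestModel on the observed phenotype
#'   scale with raw-standardized features, used by `predict()` so that
#'   predictions do not inherit the sample-space whitening scale.
#' @slot predCenters,predScales standardization constants of the raw
#'   selected-marker columns backing `predictionForest`.
#' @slot whitened the WhitenedData used by both stages.
#' @slot selected marker ids carrying importance scores.
#' @slot config the PipelineConfig used.
#' @slot seeds named integer vector of derived per-stage seeds.
#' @exportClass TslrfResult
setClass("TslrfResult",
  representation(
    importance = "ImportanceTable",
    larsPath = "LarsPath",
    varianceComponents = "VarianceComponents",
    forest = "ForestModel",
    predictionForest = "ForestModel",
    predCenters = "numeric",
    predScales = "numeric",
    whitened = "WhitenedData",
    selected = "character",
    config = "list",
    seeds = "integer"
  )
)

#' SimulationTruth: simulated phenotype with its generating ground truth
#'
#' @slot qtnIndices marker column indices of the causal QTNs.
#' @slot effects per-QTN regression coefficients b_j.
#' @slot heritabilities per-QTN target variance shares.
#' @slot geneticVariance realized variance of the genetic value.
#' @slot phenotype named length-n phenotype vector.
#' @slot genotypes the GenotypeMatrix the phenotype was simulated on.
#' @slot grandMean,residualVariance simulation constants.
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(
    qtnIndices = "integer",
    effects = "numeric",
    heritabilities = "numeric",
    geneticVariance = "numeric",
    phenotype = "numeric",
    genotypes = "GenotypeMatrix",
    grandMean = "numeric",
    residualVariance = "numeric"
  )
)

#' CVResult: ten-fold cross-validation predictions and accuracy metrics
#'
#' @slot foldAssignment length-n integer fold labels.
#' @slot predictions length-n out-of-fold predictions.
#' @slot observed length-n observed phenotypes.
#' @slot mae mean absolute error.
#' @slot mape mean absolute percentage error (fraction scale).
#' @slot pearsonR Pearson correlation of observed and predicted.
#' @slot method method evaluated.
#' @slot seed integer seed.
#' @exportClass CVResult
setClass("CVResult",
  representation(
    foldAssignment = "integer",
    predictions = "numeric",
    observed = "numeric",
    mae = "numeric",
    mape = "numeric",
    pearsonR = "numeric",
    method = "character",
    seed = "integer"
  )
)
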