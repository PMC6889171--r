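# genome segments (bp) the synthetic markers are spread over, five
# chromosome regions of an Arabidopsis-like map
simChromRanges <- data.frame(
  chrom = c("1", "2", "3", "4", "5"),
  from = c(11226256L, 5045828L, 1916588L, 2232796L, 19999868L),
  to = c(12038776L, 6412875L, 3196442L, 3143893L, 21039406L),
  stringsAsFactors = FALSE
)

# default QTN map: chromosome, bp position and per-QTN heritability
simQtnTable <- data.frame(
  chrom = c("1", "1", "2", "2", "2", "2"),
  pos = c(11298364L, 11655607L, 5066968L, 5134228L, 5464675L, 6137189L),
  h2 = c(0.10, 0.05, 0.05, 0.15, 0.05, 0.05),
  stringsAsFactors = FALSE
)

#' Simulation design
#'
#' Defaults reproduce the reference simulation study: 199 inbred
#' individuals, 10,000 biallelic SNPs at allele frequency 0.30 spread over
#' five chromosome segments, six QTNs with heritabilities
#' 0.10/0.05/0.05/0.15/0.05/0.05 placed at fixed map positions, grand mean
#' 10 and residual variance 10. Heritability is the narrow-sense variance
#' share: each QTN effect is calibrated so that `b_j^2 Var(x_j)` equals
#' `h_j^2 * sigmaP2` with `sigmaP2 = residualVariance / (1 - sum(h2))`.
#'
#' @param n samples (default 199).
#' @param p markers (default 10000).
#' @param maf minor-allele frequency of every simulated marker (default 0.30).
#' @param qtn data.frame with columns `chrom`, `pos`, `h2` (default: the
#'   six-QTN reference map); QTNs are placed on the nearest simulated marker
#'   of the same chromosome.
#' @param grandMean phenotype grand mean (default 10).
#' @param residualVariance residual variance (default 10).
#' @param polygenicLambda optional ratio sigmaG2/sigma2 for an added
#'   polygenic background term (default 0 = none).
#' @param seed master seed.
#' @return a named list of class `simConfig`.
#' @export
simConfig <- function(n = 199L, p = 10000L, maf = 0.30, qtn = simQtnTable,
                      grandMean = 10, residualVariance = 10,
                      polygenicLambda = 0, seed = 1L) {
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (sum(qtn$h2) >= 1) stop("total heritability must be below 1")
  structure(list(n = as.integer(n), p = as.integer(p), maf = maf, qtn = qtn,
                 grandMean = grandMean, residualVariance = residualVariance,
                 polygenicLambda = polygenicLambda, seed = as.integer(seed)),
            class = "simConfig")
}

#' Simulate inbred genotypes
#'
#' Independent `{0,1}`-coded markers, each column i.i.d. Bernoulli(`maf`),
#' with map positions evenly spread over five chromosome segments. Columns
#' are independent by construction: linkage disequilibrium of a real panel
#' is deliberately not emulated.
#'
#' @param n,p,maf,seed see [simConfig()].
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(n = 199L, p = 10000L, maf = 0.30, seed = 1L) {
  set.seed(seed)
  vals <- matrix(stats::rbinom(n * p, 1L, maf), n, p)
  counts <- diff(round(seq(0, p, length.out = 6L)))
  chrom <- rep(simChromRanges$chrom, counts)
  pos <- unlist(lapply(seq_len(5L), function(i) {
    if (counts[i] == 0L) return(integer(0))
    as.integer(round(seq(simChromRanges$from[i], simChromRanges$to[i],
                         length.out = counts[i])))
  }), use.names = FALSE)
  markers <- data.frame(id = make.unique(paste0("chr", chrom, "_", pos), sep = "_"),
                        chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  rownames(vals) <- sprintf("ind%03d", seq_len(n))
  GenotypeMatrix(vals, markers = markers, codeMax = 1L)
}

#' Map QTN positions onto simulated markers
#'
#' @param g a GenotypeMatrix from [simulateGenotypes()].
#' @param qtn data.frame with columns `chrom`, `pos`.
#' @return integer marker column indices (nearest same-chromosome marker).
#' @export
qtnMarkerIndices <- function(g, qtn = simQtnTable) {
  mk <- markerInfo(g)
  idx <- integer(nrow(qtn))
  for (i in seq_len(nrow(qtn))) {
    onChrom <- setdiff(which(mk$chrom == qtn$chrom[i]), idx)
    if (!length(onChrom)) stop("not enough markers on chromosome ", qtn$chrom[i])
    # nearest unused marker, so QTNs stay distinct on coarse marker grids
    idx[i] <- onChrom[which.min(abs(mk$pos[onChrom] - qtn$pos[i]))]
  }
  idx
}

#' Simulate a QTN-driven phenotype
#'
#' `y = grandMean + sum_j b_j x_j + (optional polygenic term) + e` with
#' `e ~ N(0, residualVariance)`. Effects are calibrated against the
#' realized sample variance of each QTN column so that the per-QTN variance
#' share matches its target heritability: `b_j = sqrt(h_j^2 sigmaP2 /
#' Var(x_j))` with `sigmaP2 = residualVariance / (1 - sum h2)`. When
#' `polygenicLambda > 0`, a polygenic effect `u ~ MVN(0, lambda sigma2 K)`
#' with `K` computed from the simulated markers is added.
#'
#' @param g a [GenotypeMatrix-class] without missing calls.
#' @param cfg a [simConfig()]; `cfg$seed` drives the residual draw.
#' @return a [SimulationTruth-class].
#' @export
simulatePhenotype <- function(g, cfg = simConfig()) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (sum(cfg$qtn$h2) >= 1) stop("total heritability must be below 1")
  qtnIdx <- qtnMarkerIndices(g, cfg$qtn)
  Z <- genotypes(g)[, qtnIdx, drop = FALSE]
  v <- apply(Z, 2, stats::var)
  if (any(v <= 0)) stop("a QTN column is monomorphic; re-simulate genotypes")
  sigmaP2 <- cfg$residualVariance / (1 - sum(cfg$qtn$h2))
  b <- sqrt(cfg$qtn$h2 * sigmaP2 / v)
  gv <- as.numeric(Z %*% b)
  set.seed(deriveSeed(cfg$seed, "phenotype"))
  yres <- stats::rnorm(nSamples(g), 0, sqrt(cfg$residualVariance))
  u <- 0
  if (cfg$polygenicLambda > 0) {
    K <- kinshipValues(computeKinship(g))
    eg <- eigen(K, symmetric = TRUE)
    sdv <- sqrt(pmax(eg$values, 0) * cfg$polygenicLambda * cfg$residualVariance)
    u <- as.numeric(eg$vectors %*% (sdv * stats::rnorm(nSamples(g))))
  }
  y <- cfg$grandMean + gv + u + yres
  names(y) <- sampleIds(g)
  new("SimulationTruth", qtnIndices = as.integer(qtnIdx), effects = b,
      heritabilities = cfg$qtn$h2, geneticVariance = stats::var(gv),
      phenotype = y, genotypes = g, grandMean = cfg$grandMean,
      residualVariance = cfg$residualVariance)
}

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf("SimulationTruth: %d samples, %d QTNs (h2: %s)\n",
              length(object@phenotype), length(object@qtnIndices),
              paste(object@heritabilities, collapse = "/")))
  cat(sprintf("  realized genetic variance %.3f, phenotype variance %.3f\n",
              object@geneticVariance, stats::var(object@phenotype)))
})

#' Simulate one complete replicate (genotypes + phenotype)
#'
#' @param cfg a [simConfig()].
#' @return a [SimulationTruth-class].
#' @export
simulateReplicate <- function(cfg = simConfig()) {
  g <- simulateGenotypes(cfg$n, cfg$p, cfg$maf,
                         seed = deriveSeed(cfg$seed, "genotypes"))
  simulatePhenotype(g, cfg)
}

#' Replicated simulation study
#'
#' Runs fresh simulated replicates through the requested methods and
#' aggregates per-QTN importance scores, top-QTN / six-QTN / unrelated-SNP
#' summaries and (optionally) ten-fold cross-validation accuracy metrics.
#' Markers not scored by a method count as score 0 in the summaries.
#' Replicate seeds are derived deterministically from `seed`.
#'
#' @param nReps number of replicates.
#' @param cfg a [simConfig()] (its `seed` is overridden per replicate).
#' @param methods subset of `"tslrf"`, `"rf"`, `"tsrf"`.
#' @param seed master seed.
#' @param pipelineCfg a [tslrfConfig()] template (its seed is overridden).
#' @param cv also run ten-fold cross-validation per replicate (slow).
#' @param groupSize TSRF comparator group size.
#' @return list with elements `perQtn` (per-method list of nReps x 6 score
#'   matrices), `qtnSummary` (per-QTN mean and SD per method), `summary`
#'   (per method: mean score of the on-average top-ranked QTN, mean of the
#'   per-replicate best QTN score, six-QTN mean, unrelated-SNP mean),
#'   `fitR` (mean in-sample Pearson r, TSLRF only), `cvMetrics` (when
#'   `cv = TRUE`), and `failures` (count of replicates skipped on error).
#' @export
replicateStudy <- function(nReps, cfg = simConfig(),
                           methods = c("tslrf"), seed = 1L,
                           pipelineCfg = tslrfConfig(), cv = FALSE,
                           groupSize = 1000L) {
  methods <- match.arg(methods, c("tslrf", "rf", "tsrf"), several.ok = TRUE)
  perQtn <- lapply(methods, function(m) matrix(NA_real_, nReps, nrow(cfg$qtn)))
  names(perQtn) <- methods
  unrel <- matrix(NA_real_, nReps, length(methods), dimnames = list(NULL, methods))
  fitR <- rep(NA_real_, nReps)
  cvRows <- list()
  failures <- 0L
  for (r in seq_len(nReps)) {
    repSeed <- deriveSeed(seed, paste0("rep", r))
    simCfgR <- cfg
    simCfgR$seed <- repSeed
    truth <- tryCatch(simulateReplicate(simCfgR), error = function(e) NULL)
    if (is.null(truth)) { failures <- failures + 1L; next }
    qtnIds <- markerIds(truth@genotypes)[truth@qtnIndices]
    pc <- pipelineCfg
    pc$seed <- repSeed
    for (m in methods) {
      res <- tryCatch(switch(m,
        tslrf = runTslrf(truth@genotypes, truth@phenotype, pc),
        rf = runRfBaseline(truth@genotypes, truth@phenotype, pc),
        tsrf = runTsrfComparator(truth@genotypes, truth@phenotype, pc,
                                 groupSize = groupSize)
      ), error = function(e) { warning(conditionMessage(e)); NULL })
      if (is.null(res)) { failures <- failures + 1L; next }
      tab <- importanceTable(res)
      sc <- stats::setNames(rep(0, nMarkers(truth@genotypes)),
                            markerIds(truth@genotypes))
      scored <- !is.na(tab$score)
      sc[tab$marker_id[scored]] <- tab$score[scored]
      perQtn[[m]][r, ] <- sc[qtnIds]
      unrel[r, m] <- mean(sc[setdiff(names(sc), qtnIds)])
      if (m == "tslrf") {
        sel <- res@selected
        fitted <- predict(res@forest, res@whitened@X[, sel, drop = FALSE])
        fitR[r] <- pearsonR(truth@phenotype, fitted)
      }
      if (cv) {
        cvr <- tenFoldCv(truth@genotypes, truth@phenotype, pc, method = m,
                         seed = deriveSeed(repSeed, "cv"))
        cvRows[[length(cvRows) + 1L]] <-
          data.frame(rep = r, method = m, mae = cvr@mae, mape = cvr@mape,
                     pearson_r = cvr@pearsonR)
      }
    }
  }
  qtnSummary <- do.call(rbind, lapply(methods, function(m) {
    data.frame(method = m, qtn = seq_len(nrow(cfg$qtn)),
               chrom = cfg$qtn$chrom, pos = cfg$qtn$pos, h2 = cfg$qtn$h2,
               meanScore = colMeans(perQtn[[m]], na.rm = TRUE),
               sdScore = apply(perQtn[[m]], 2, stats::sd, na.rm = TRUE))
  }))
  summary <- do.call(rbind, lapply(methods, function(m) {
    tops <- apply(perQtn[[m]], 1, max)
    data.frame(method = m,
               # mean score of the QTN that ranks top on average ...
               topRankedQtn = max(colMeans(perQtn[[m]], na.rm = TRUE)),
               # ... and the mean of the per-replicate best QTN score
               topQtnPerRep = mean(tops, na.rm = TRUE),
               sixQtnMean = mean(perQtn[[m]], na.rm = TRUE),
               unrelatedMean = mean(unrel[, m], na.rm = TRUE))
  }))
  list(perQtn = perQtn, qtnSummary = qtnSummary, summary = summary,
       fitR = mean(fitR, na.rm = TRUE),
       cvMetrics = if (length(cvRows)) do.call(rbind, cvRows) else NULL,
       failures = failures)
}
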