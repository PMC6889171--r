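#' Compute a genomic relationship (kinship) matrix
#'
#' VanRaden-style standardized cross-product: each marker column is centered
#' and scaled to unit variance, monomorphic columns are excluded, and
#' `K = M M' / p` over the `p` retained markers. The result is symmetric
#' positive semidefinite with mean diagonal near 1 for unrelated samples.
#'
#' @param g an imputed [GenotypeMatrix-class] (no missing calls).
#' @return a [KinshipMatrix-class] aligned with `sampleIds(g)`.
#' @export
computeKinship <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (any(g@missing)) stop("genotypes must be imputed before computeKinship()")
  Z <- g@genotypes
  sds <- apply(Z, 2, stats::sd)
  keep <- sds > 1e-12
  if (!any(keep)) stop("no polymorphic markers available for kinship")
  M <- scale(Z[, keep, drop = FALSE])
  K <- tcrossprod(M) / sum(keep)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(Z), rownames(Z))
  new("KinshipMatrix", values = K)
}

#' @rdname KinshipMatrix-class
setMethod("kinshipValues", "KinshipMatrix", function(x) x@values)

setMethod("show", "KinshipMatrix", function(object) {
  K <- object@values
  cat(sprintf("KinshipMatrix: %d samples, mean diagonal %.3f\n",
              nrow(K), mean(diag(K))))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(paste0("VarianceComponents: sigmaG2 = %.4g, sigma2 = %.4g, ",
                     "lambda = %.4g (REML logLik %.3f)%s\n"),
              object@sigmaG2, object@sigma2, object@lambda, object@remlLogLik,
              if (object@boundary) " [boundary]" else ""))
})

remlProfile <- function(lambda, ev, Uty, UtW, n, c, logDetWtW) {
  d <- lambda * ev + 1
  UtWd <- UtW / d
  WtViW <- crossprod(UtW, UtWd)
  WtViy <- crossprod(UtWd, Uty)
  ytViy <- sum(Uty^2 / d)
  ch <- tryCatch(chol(WtViW), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  ytPy <- ytViy - sum(backsolve(ch, WtViy, transpose = TRUE)^2)
  if (ytPy <= 0) return(-Inf)
  s2 <- ytPy / (n - c)
  -0.5 * ((n - c) * log(2 * pi * s2) + sum(log(d)) +
          2 * sum(log(diag(ch))) - logDetWtW + (n - c))
}

#' REML variance components of the polygenic null model
#'
#' Fits `y = W alpha + u + e` with `u ~ MVN(0, sigmaG2 K)` and
#' `e ~ MVN(0, sigma2 I)` by restricted maximum likelihood, profiling the
#' likelihood in `lambda = sigmaG2/sigma2` via the spectral decomposition of
#' `K`: a 100-point log-spaced grid on `[1e-5, 1e5]` followed by bounded
#' scalar refinement (tolerance 1e-6 on log-lambda). `sigma2` is recovered
#' in closed form at the optimum.
#'
#' When the profile is flat (e.g. `K` proportional to the identity) lambda
#' is unidentifiable; the estimate is pinned at the lower search bound with
#' a warning and the `boundary` flag set.
#'
#' @param y named numeric phenotype (missing entries dropped with their
#'   samples).
#' @param k a [KinshipMatrix-class] covering the samples of `y`.
#' @param fixedDesign fixed-effect design matrix (default: intercept only).
#'   Must have full column rank.
#' @param bounds search interval for lambda.
#' @param gridPoints number of profile grid points.
#' @return a [VarianceComponents-class].
#' @export
estimateVarianceComponents <- function(y, k, fixedDesign = NULL,
                                       bounds = c(1e-5, 1e5),
                                       gridPoints = 100L) {
  stopifnot(is(k, "KinshipMatrix"))
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  if (n < 10) stop("need at least 10 non-missing phenotypes")
  if (stats::var(y) <= 0) stop("phenotype has zero variance")
  K <- k@values
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    if (!all(names(y) %in% rownames(K))) stop("kinship does not cover all samples")
    K <- K[names(y), names(y)]
  } else if (any(!keep)) {
    K <- K[keep, keep]
  }
  if (is.null(fixedDesign)) fixedDesign <- matrix(1, n, 1)
  W <- as.matrix(fixedDesign)
  c <- ncol(W)
  if (qr(W)$rank < c) stop("fixed-effect design is rank deficient")
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(1, max(abs(eg$values)))) {
    stop("kinship matrix is not positive semidefinite")
  }
  ev <- pmax(eg$values, 0)
  Uty <- as.numeric(crossprod(eg$vectors, y))
  UtW <- crossprod(eg$vectors, W)
  logDetWtW <- as.numeric(determinant(crossprod(W), logarithm = TRUE)$modulus)
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = gridPoints))
  ll <- vapply(grid, remlProfile, 0, ev = ev, Uty = Uty, UtW = UtW,
               n = n, c = c, logDetWtW = logDetWtW)
  boundary <- FALSE
  if (max(ll) - min(ll) < 1e-8) {
    warning("REML profile is flat in lambda (unidentifiable); returning the lower bound")
    lamHat <- bounds[1]
    boundary <- TRUE
    llHat <- ll[1]
  } else {
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(ll10) {
      remlProfile(exp(ll10), ev, Uty, UtW, n, c, logDetWtW)
    }, lower = log(lo), upper = log(hi), maximum = TRUE, tol = 1e-6)
    lamHat <- exp(opt$maximum)
    llHat <- opt$objective
    if (llHat < ll[i]) {  # refinement must never lose to the grid
      lamHat <- grid[i]
      llHat <- ll[i]
    }
    if (i == 1L || i == length(grid)) boundary <- TRUE
  }
  d <- lamHat * ev + 1
  UtWd <- UtW / d
  WtViW <- crossprod(UtW, UtWd)
  WtViy <- crossprod(UtWd, Uty)
  ytPy <- sum(Uty^2 / d) - sum(backsolve(chol(WtViW), WtViy, transpose = TRUE)^2)
  s2 <- as.numeric(ytPy / (n - c))
  new("VarianceComponents", sigmaG2 = lamHat * s2, sigma2 = s2,
      lambda = lamHat, remlLogLik = as.numeric(llHat), boundary = boundary)
}

#' REML profile log-likelihood at given lambda values
#'
#' Exposes the profiled restricted log-likelihood used by
#' [estimateVarianceComponents()], mainly for diagnostics and testing.
#'
#' @param lambda numeric vector of variance ratios.
#' @inheritParams estimateVarianceComponents
#' @return numeric vector of restricted log-likelihoods.
#' @export
remlLogLikelihood <- function(lambda, y, k, fixedDesign = NULL) {
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  K <- k@values
  if (!is.null(names(y)) && !is.null(rownames(K))) K <- K[names(y), names(y)]
  if (is.null(fixedDesign)) fixedDesign <- matrix(1, n, 1)
  W <- as.matrix(fixedDesign)
  eg <- eigen(K, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  Uty <- as.numeric(crossprod(eg$vectors, y))
  UtW <- crossprod(eg$vectors, W)
  logDetWtW <- as.numeric(determinant(crossprod(W), logarithm = TRUE)$modulus)
  vapply(lambda, remlProfile, 0, ev = ev, Uty = Uty, UtW = UtW,
         n = n, c = ncol(W), logDetWtW = logDetWtW)
}

#' Whitening transform of phenotype, markers and fixed effects
#'
#' Builds `C = (lambda K + I)^(-1/2)` from the eigendecomposition of `K` and
#' applies it to the phenotype (`Y = C y`), the raw marker columns and the
#' fixed-effect design. Transformed marker columns are then centered to sum
#' zero and scaled to unit sum of squares; columns that become constant are
#' dropped with a warning. After the transform the model residual covariance
#' is `sigma2 * I` by construction.
#'
#' @param y named numeric phenotype vector.
#' @param g an imputed [GenotypeMatrix-class] on the same samples.
#' @param k a [KinshipMatrix-class].
#' @param vc [VarianceComponents-class] from [estimateVarianceComponents()]
#'   on the same `(y, k)`.
#' @param fixedDesign fixed-effect design (default intercept).
#' @return a [WhitenedData-class].
#' @export
whiten <- function(y, g, k, vc, fixedDesign = NULL) {
  stopifnot(is(g, "GenotypeMatrix"), is(k, "KinshipMatrix"),
            is(vc, "VarianceComponents"))
  if (any(g@missing)) stop("genotypes must be imputed before whiten()")
  n <- nSamples(g)
  if (length(y) != n) stop("phenotype length must match sample count")
  K <- k@values
  lam <- vc@lambda
  eg <- eigen(K, symmetric = TRUE)
  d <- lam * eg$values + 1
  if (min(d) < 1e-10) stop("lambda*K + I is numerically singular")
  C <- eg$vectors %*% (t(eg$vectors) / sqrt(d))
  C <- (C + t(C)) / 2
  Y <- as.numeric(C %*% y)
  names(Y) <- names(y)
  if (is.null(fixedDesign)) fixedDesign <- matrix(1, n, 1)
  W <- C %*% as.matrix(fixedDesign)
  CZ <- C %*% g@genotypes
  centers <- colMeans(CZ)
  Xc <- sweep(CZ, 2, centers)
  ss <- sqrt(colSums(Xc^2))
  keep <- ss > 1e-8
  if (!all(keep)) {
    warning(sprintf("dropping %d constant column(s) after transformation",
                    sum(!keep)))
  }
  X <- sweep(Xc[, keep, drop = FALSE], 2, ss[keep], "/")
  colnames(X) <- markerIds(g)[keep]
  new("WhitenedData", Y = Y, X = X, transform = C, fixedDesign = W,
      centers = centers[keep], scales = ss[keep],
      dropped = markerIds(g)[!keep])
}

setMethod("show", "WhitenedData", function(object) {
  cat(sprintf("WhitenedData: %d samples x %d standardized markers (%d dropped)\n",
              nrow(object@X), ncol(object@X), length(object@dropped)))
})
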