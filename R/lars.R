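#' Least Angle Regression path
#'
#' Forward LARS over a standardized design: at each step the variable(s)
#' most correlated in absolute value with the current residual join the
#' active set, and the fit moves along the equiangular direction of the
#' active set exactly until an inactive variable ties the common absolute
#' correlation. The procedure saturates after at most `n - 1` steps.
#'
#' Ties within `1e-10` of the maximum correlation are broken by lowest
#' column index. Variables that would make the active Gram matrix singular
#' (e.g. duplicated columns) are excluded with a warning and the path
#' continues without them. The response is centered internally (the
#' intercept is projected out before screening).
#'
#' @param X design matrix whose columns are centered (sum 0) and unit-norm
#'   (sum of squares 1); a precondition error is raised otherwise.
#' @param Y numeric response.
#' @param maxSteps maximum number of steps, at most `n - 1` (default).
#' @param sigmaBar2 residual-variance estimate for the Cp trace; defaults to
#'   the sample variance of the centered response (null-model estimate).
#' @return a [LarsPath-class] with the entry order, per-step coefficients
#'   (standardized scale), RSS and Cp traces.
#' @seealso [cpStatistic()], [selectVariables()]
#' @export
larsPath <- function(X, Y, maxSteps = nrow(X) - 1L, sigmaBar2 = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(Y) != n) stop("response length must match rows of X")
  if (maxSteps > n - 1L) stop("maxSteps must not exceed n - 1")
  cs <- colSums(X)
  ss <- colSums(X^2)
  if (max(abs(cs)) > 1e-6 || max(abs(ss - 1)) > 1e-6) {
    stop("columns of X must be centered and unit-norm (see whiten())")
  }
  Y <- Y - mean(Y)
  if (is.null(sigmaBar2)) sigmaBar2 <- stats::var(Y)
  if (sigmaBar2 <= 0) stop("sigmaBar2 must be positive")

  maxSteps <- min(maxSteps, p)
  mu <- numeric(n)
  beta <- numeric(p)
  active <- integer(0)
  ignored <- integer(0)
  rss <- numeric(0)
  coefSnaps <- list()
  # Gram over the unsigned active columns, grown incrementally
  G <- matrix(0, 0, 0)
  tieTol <- 1e-10

  while (length(active) < maxSteps) {
    r <- Y - mu
    cvec <- as.numeric(crossprod(X, r))
    cand <- setdiff(seq_len(p), c(active, ignored))
    if (!length(cand)) break
    Cmax <- max(abs(cvec[cand]))
    if (Cmax < 1e-8) break
    entering <- cand[abs(cvec[cand]) >= Cmax - tieTol]
    entering <- sort(entering)
    room <- maxSteps - length(active)
    if (length(entering) > room) entering <- entering[seq_len(room)]

    # grow the Gram matrix, rejecting entrants that make it singular
    for (j in entering) {
      gj <- as.numeric(crossprod(X[, c(active, j), drop = FALSE], X[, j]))
      k <- length(active)
      Gnew <- rbind(cbind(G, gj[seq_len(k)]), c(gj[seq_len(k)], gj[k + 1L]))
      ch <- tryCatch(chol(Gnew), error = function(e) NULL)
      if (is.null(ch)) {
        warning(sprintf("column %d is collinear with the active set; excluded", j))
        ignored <- c(ignored, j)
      } else {
        G <- Gnew
        active <- c(active, j)
      }
    }
    k <- length(active)
    if (!k) break
    sgn <- sign(cvec[active])
    Gs <- G * tcrossprod(sgn)
    w0 <- solve(Gs, rep(1, k))
    A <- 1 / sqrt(sum(w0))
    w <- A * w0
    u <- as.numeric(X[, active, drop = FALSE] %*% (sgn * w))
    gammaMax <- Cmax / A
    cand <- setdiff(seq_len(p), c(active, ignored))
    if (length(cand)) {
      a <- as.numeric(crossprod(X[, cand, drop = FALSE], u))
      t1 <- (Cmax - cvec[cand]) / (A - a)
      t2 <- (Cmax + cvec[cand]) / (A + a)
      tt <- c(t1, t2)
      tt <- tt[is.finite(tt) & tt > tieTol]
      gamma <- min(c(tt, gammaMax))
    } else {
      gamma <- gammaMax
    }
    beta[active] <- beta[active] + gamma * sgn * w
    mu <- mu + gamma * u
    rssNow <- sum((Y - mu)^2)
    rss <- c(rss, rssNow)
    coefSnaps[[length(coefSnaps) + 1L]] <- beta[active]
    if (rssNow < 1e-12) break
  }

  sMax <- length(rss)
  coefMat <- matrix(0, sMax, length(active))
  for (s in seq_len(sMax)) {
    coefMat[s, seq_along(coefSnaps[[s]])] <- coefSnaps[[s]]
  }
  colnames(coefMat) <- colnames(X)[active]
  steps <- vapply(seq_len(sMax), function(s) length(coefSnaps[[s]]), 0L)
  cp <- vapply(seq_len(sMax), function(s) {
    cpStatistic(rss[s], sigmaBar2, n, steps[s])
  }, 0)
  new("LarsPath", activeOrder = as.integer(active), coefficients = coefMat,
      rssTrace = rss, cpTrace = cp, sMax = as.integer(sMax),
      stepSizes = steps, sigmaBar2 = sigmaBar2,
      markerIds = if (is.null(colnames(X))) character(0) else colnames(X))
}

#' Cp-type risk estimate of an s-step LARS fit
#'
#' `Cp = RSS_s / sigmaBar2 - n + 2 s`. With the screen run to saturation
#' the statistic is diagnostic rather than a stopping rule; the
#' residual-variance estimate defaults (in [larsPath()]) to the null-model
#' sample variance of the response because a full ordinary-least-squares
#' estimate does not exist when p exceeds n.
#'
#' @param rss residual sum of squares at step `s`.
#' @param sigmaBar2 residual-variance estimate (> 0).
#' @param n sample size.
#' @param s step number (variables in the active set).
#' @return the Cp value.
#' @export
cpStatistic <- function(rss, sigmaBar2, n, s) {
  if (sigmaBar2 <= 0) stop("sigmaBar2 must be positive")
  if (s < 0 || s > n - 1) stop("s must lie in [0, n-1]")
  rss / sigmaBar2 - n + 2 * s
}

#' First k variables of a LARS path
#'
#' @param path a [LarsPath-class].
#' @param k number of variables (default: all entered, at most `n - 1`).
#' @return integer vector of design-column indices in entry order.
#' @export
selectVariables <- function(path, k = length(path@activeOrder)) {
  stopifnot(is(path, "LarsPath"))
  if (k > length(path@activeOrder)) {
    stop("k exceeds the number of variables on the path")
  }
  path@activeOrder[seq_len(k)]
}

setMethod("show", "LarsPath", function(object) {
  cat(sprintf("LarsPath: %d steps, %d active variables\n",
              object@sMax, length(object@activeOrder)))
  if (object@sMax) {
    cat(sprintf("  final RSS %.4g, min Cp %.4g at step %d\n",
                object@rssTrace[object@sMax], min(object@cpTrace),
                which.min(object@cpTrace)))
  }
})

#' Write a per-step LARS trace
#'
#' Tab-delimited dump with columns step, entering_marker, rss, cp.
#'
#' @param path a [LarsPath-class].
#' @param file output path.
#' @export
writeLarsTrace <- function(path, file) {
  stopifnot(is(path, "LarsPath"))
  ids <- if (ncol(path@coefficients) && !is.null(colnames(path@coefficients))) {
    colnames(path@coefficients)
  } else as.character(path@activeOrder)
  nz <- path@stepSizes
  lines <- c("step\tentering_marker\trss\tcp",
             vapply(seq_len(path@sMax), function(s) {
               newIdx <- if (s == 1L) seq_len(nz[1]) else setdiff(seq_len(nz[s]), seq_len(nz[s - 1L]))
               paste(s, paste(ids[newIdx], collapse = ","),
                     format(path@rssTrace[s], digits = 10),
                     format(path@cpTrace[s], digits = 10), sep = "\t")
             }, ""))
  writeLines(lines, file)
  invisible(file)
}
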