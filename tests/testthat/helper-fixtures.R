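# Small in-code fixtures shared across test files.

toyGenotypes <- function(n = 20, p = 50, maf = 0.3, seed = 1, missingRate = 0,
                         codeMax = 1L) {
  set.seed(seed)
  vals <- matrix(rbinom(n * p, codeMax, maf), n, p)
  if (missingRate > 0) {
    vals[matrix(runif(n * p) < missingRate, n, p)] <- NA
  }
  rownames(vals) <- sprintf("s%03d", seq_len(n))
  colnames(vals) <- sprintf("m%03d", seq_len(p))
  GenotypeMatrix(vals, codeMax = codeMax)
}

# center + unit-norm columns, dropping constants; for LARS inputs
stdCols <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  ss <- sqrt(colSums(Xc^2))
  keep <- ss > 1e-10
  sweep(Xc[, keep, drop = FALSE], 2, ss[keep], "/")
}

# closed-form LARS coefficients for an orthonormal centered design:
# variables enter by decreasing |c_j|, and after step s each active
# coefficient is soft-thresholded at the (s+1)-th largest |c|
orthoLarsOracle <- function(X, Y) {
  cvec <- as.numeric(crossprod(X, Y - mean(Y)))
  ord <- order(-abs(cvec))
  thresholds <- c(abs(cvec)[ord][-1], 0)
  lapply(seq_along(ord), function(s) {
    idx <- ord[seq_len(s)]
    setNames(sign(cvec[idx]) * (abs(cvec[idx]) - thresholds[s]), idx)
  })
}

expect_identical_genotypes <- function(a, b) {
  expect_equal(genotypes(a), genotypes(b))
  expect_equal(markerInfo(a), markerInfo(b))
  expect_equal(missingMask(a), missingMask(b))
}
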