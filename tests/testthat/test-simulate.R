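test_that("genotype simulation is reproducible and hits the target frequency", {
  g1 <- simulateGenotypes(n = 199, p = 10000, maf = 0.30, seed = 5)
  g2 <- simulateGenotypes(n = 199, p = 10000, maf = 0.30, seed = 5)
  expect_identical(genotypes(g1), genotypes(g2))
  expect_equal(mean(colMeans(genotypes(g1))), 0.30, tolerance = 0.01 / 0.30)
  expect_equal(sort(unique(markerInfo(g1)$chrom)), as.character(1:5))
  mk <- markerInfo(g1)
  expect_true(all(tapply(mk$pos, mk$chrom, function(p) !is.unsorted(p))))
})

test_that("simulated markers are essentially uncorrelated", {
  g <- simulateGenotypes(n = 199, p = 200, maf = 0.30, seed = 6)
  R <- cor(genotypes(g))
  expect_lt(mean(abs(R[upper.tri(R)])), 0.08)
})

test_that("QTN positions map to the nearest same-chromosome markers", {
  g <- simulateGenotypes(n = 30, p = 500, seed = 7)
  idx <- qtnMarkerIndices(g)
  mk <- markerInfo(g)
  expect_length(idx, 6)
  expect_equal(mk$chrom[idx], c("1", "1", "2", "2", "2", "2"))
  # nearest: no other marker on the chromosome is closer to the target bp
  qtn <- tslrf:::simQtnTable
  for (i in seq_len(6)) {
    onChrom <- which(mk$chrom == qtn$chrom[i])
    expect_equal(min(abs(mk$pos[onChrom] - qtn$pos[i])),
                 abs(mk$pos[idx[i]] - qtn$pos[i]))
  }
})

test_that("zero heritability gives pure gaussian noise around the grand mean", {
  cfg <- simConfig(n = 199, p = 60, seed = 8,
                   qtn = within(tslrf:::simQtnTable, h2 <- rep(0, 6)))
  truth <- simulateReplicate(cfg)
  expect_true(all(truth@effects == 0))
  v <- var(truth@phenotype)
  expect_gt(v, 8); expect_lt(v, 12)
  expect_equal(mean(truth@phenotype), 10, tolerance = 0.1)
})

test_that("the default design realizes the prescribed phenotypic variance", {
  # sigmaP2 = residualVariance / (1 - sum h2) = 10 / 0.55
  expect_equal(10 / 0.55, 18.18, tolerance = 1e-3)
  vs <- vapply(1:20, function(r) {
    var(simulateReplicate(simConfig(n = 199, p = 300, seed = 40 + r))@phenotype)
  }, 0)
  # sd of a sample variance at n = 199 is ~ sqrt(2 * 18.18^2 / 198) = 1.83;
  # per-replicate band is the 3-sigma envelope around 18.18
  expect_true(all(vs > 12.5 & vs < 23.9))
  expect_equal(mean(vs), 18.18, tolerance = 0.1)
})

test_that("regression on the true QTNs recovers the total heritability", {
  r2 <- vapply(1:50, function(r) {
    truth <- simulateReplicate(simConfig(n = 199, p = 300, seed = 700 + r))
    X <- genotypes(truth@genotypes)[, truth@qtnIndices]
    summary(lm(truth@phenotype ~ X))$r.squared
  }, 0)
  expect_equal(mean(r2), 0.45, tolerance = 0.05 / 0.45)
})

test_that("per-QTN effect sizes are calibrated to their heritability targets", {
  shares <- vapply(1:200, function(r) {
    truth <- simulateReplicate(simConfig(n = 199, p = 120, seed = 2000 + r))
    x4 <- genotypes(truth@genotypes)[, truth@qtnIndices[4]]
    truth@effects[4]^2 * var(x4) / var(truth@phenotype)
  }, 0)
  expect_equal(mean(shares), 0.15, tolerance = 0.02 / 0.15)
})

test_that("an optional polygenic background term adds covariance", {
  cfg0 <- simConfig(n = 60, p = 200, seed = 9)
  cfgL <- simConfig(n = 60, p = 200, seed = 9, polygenicLambda = 5)
  t0 <- simulateReplicate(cfg0)
  tL <- simulateReplicate(cfgL)
  expect_gt(var(tL@phenotype), var(t0@phenotype))
})

test_that("replicateStudy aggregates per-QTN scores deterministically", {
  cfg <- simConfig(n = 40, p = 80, seed = 1)
  pc <- tslrfConfig(ntree = 60)
  s1 <- replicateStudy(2, cfg, methods = c("tslrf", "rf"), seed = 5,
                       pipelineCfg = pc)
  s2 <- replicateStudy(2, cfg, methods = c("tslrf", "rf"), seed = 5,
                       pipelineCfg = pc)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$qtnSummary, s2$qtnSummary)
  expect_equal(nrow(s1$qtnSummary), 12)  # 6 QTNs x 2 methods
  expect_equal(dim(s1$perQtn$tslrf), c(2, 6))
  expect_equal(s1$failures, 0)
  # summary means must equal manual aggregation of the per-replicate matrix
  expect_equal(s1$summary$sixQtnMean[s1$summary$method == "tslrf"],
               mean(s1$perQtn$tslrf))
  expect_equal(s1$summary$topQtnPerRep[s1$summary$method == "tslrf"],
               mean(apply(s1$perQtn$tslrf, 1, max)))
  expect_equal(s1$summary$topRankedQtn[s1$summary$method == "tslrf"],
               max(colMeans(s1$perQtn$tslrf)))
})
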