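---
title: "Two-stage SNP prioritization: model, assumptions and design choices"
author: "tslrf maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage SNP prioritization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tslrf)
```

## The problem

Association scans for quantitative traits face two structural difficulties.
First, marker panels are far wider than they are deep (thousands to hundreds
of thousands of SNPs against a few hundred individuals), so single-marker
statistics are noisy and joint models are underdetermined. Second, in
natural or breeding populations the samples are related: polygenic
background and population structure induce phenotypic covariance that
single-marker and naive machine-learning rankings both mistake for signal.

`tslrf` addresses both at once with a three-part procedure:

1. **Background correction (whitening).** The null mixed model
   `y = W alpha + u + e`, with polygenic effect `u ~ MVN(0, sigmaG2 K)` over
   a kinship matrix `K` and residual `e ~ MVN(0, sigma2 I)`, is fitted by
   REML. With `lambda = sigmaG2 / sigma2`, the transform
   `C = (lambda K + I)^(-1/2)` is applied to the phenotype, the marker
   columns and the fixed-effect design. After the transform the model
   residual covariance is spherical, so subsequent least-squares machinery
   sees exchangeable noise. Transformed marker columns are standardized to
   sum zero and unit sum of squares.
2. **Screening (Least Angle Regression).** LARS is run on the standardized,
   whitened markers against the corrected phenotype. LARS adds, at each
   step, the variable most correlated in absolute value with the current
   residual and moves along the equiangular direction of the active set
   until an inactive variable ties. It saturates after at most `n - 1`
   steps, which bounds the screened set at `n - 1` SNPs regardless of `p`.
   The screen is run to saturation by default; the per-step Cp trace
   (`RSS/sigmaBar2 - n + 2s`) is recorded as a diagnostic.
3. **Ranking (random forest).** A bagged regression forest with random
   node subspaces is fitted to the screened SNPs, `mtry` tuned by
   out-of-bag (OOB) mean squared error, and every screened SNP is scored by
   permutation importance: the mean increase in per-tree OOB MSE after
   permuting the SNP, divided by its standard error (%IncMSE). The score
   ranking is the result of the method.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `mafThreshold` | 0.10 | markers with minor-allele frequency below 10% are removed before analysis; rare markers carry unstable importance scores |
| `larsMaxSteps` | `n - 1` | the saturated screen; with fewer steps the forest sees a smaller candidate set |
| `ntree` | 500 | classical regression-forest default; importance stabilizes well before this at `k <= n - 1` variables |
| `mtryGrid` | `{k/3, sqrt(k), k/2, k}` | OOB-tuned per dataset; OOB MSE is the internal, leakage-free fitting criterion |
| `lambda` search | `[1e-5, 1e5]`, 100-point log grid + bounded refinement | the profiled REML surface in `lambda` is cheap on the spectral decomposition of `K`; tolerance 1e-6 on `log(lambda)` |
| `permutations` | 1 | one permutation per tree, the classical importance estimator; more draws average additional forest realizations |

Kinship is the VanRaden-style standardized cross-product `K = M M' / p`
over centered, unit-variance marker columns. It is phenotype-free, so in
cross-validation it may be computed once per training fold without leaking
test information.

## The simulation design

The generator emulates the reference design under which the method's
operating characteristics are quantified: `n = 199` inbred individuals,
`p = 10000` biallelic SNPs coded `{0,1}`, every column i.i.d.
Bernoulli(0.30), markers laid out over five chromosome segments; six QTNs
at fixed map positions (two on chromosome 1, four on chromosome 2) with
heritabilities 0.10, 0.05, 0.05, 0.15, 0.05, 0.05; grand mean 10 and
residual variance 10. Effects are calibrated against the realized sample
variance of each QTN column, `b_j = sqrt(h_j^2 sigmaP2 / Var(x_j))` with
`sigmaP2 = 10 / (1 - 0.55) = 18.18`, so each QTN's variance share matches
its target heritability in expectation.

What the generator deliberately does **not** emulate is linkage
disequilibrium: real panels carry blocks of correlated markers, whereas the
simulated columns are independent. This matters for interpreting results.
With LD, the signal of a strong QTN is shared across its correlated
neighbours, which both depresses the QTN's own importance score and raises
the scores of hitchhiking SNPs. With independent columns the entire signal
concentrates on the causal column, so the top QTN's importance score runs
higher here than it would on a real panel, while the gap between QTNs and
null SNPs is, if anything, cleaner. Passing the simulation suite therefore
demonstrates correct mechanics and calibrated power ordering, not exact
score magnitudes on LD-structured data.

A polygenic background term is off by default (`polygenicLambda = 0`): the
reference design lists only QTN effects plus residual noise. It can be
switched on to stress the whitening stage, and the REML recovery tests do
exactly that.

## Numerical choices and degenerate inputs

* **Identifiability.** When `K` is (close to) the identity, `lambda` is
  unidentifiable - the REML profile is flat - and the estimate is pinned to
  the lower search bound with a warning rather than reported as meaningful.
* **Eigenvalue guards.** `K` is accepted when its smallest eigenvalue is
  above `-1e-8`; eigenvalues of `lambda K + I` below `1e-10` abort the
  whitening with a numerical error.
* **Constant columns.** Marker columns that become constant after the
  transform cannot be standardized to unit norm and are dropped with a
  warning, not zero-filled.
* **LARS ties and collinearity.** Ties in the entry correlation within
  `1e-10` are broken by lowest column index (determinism); a variable that
  would make the active Gram matrix singular (duplicated columns) is
  excluded with a warning and the path continues. The pure forward LARS
  procedure is used: no lasso-style sign-change drops.
* **Cp's variance estimate.** The Cp formula needs a residual-variance
  estimate from the full least-squares model, which does not exist for
  `p > n`. The package substitutes the null-model estimate (the sample
  variance of the corrected phenotype) and treats Cp as a monotone
  diagnostic rather than a stopping rule, since the screen is run to
  saturation anyway. On saturated runs the literal formula makes the
  attainable minimum `n - 2 + RSS/sigmaBar2`; the trace is reported as
  defined, without adjustment.
* **Intercept handling.** The transformed fixed-effect design (intercept at
  minimum) is projected out of the corrected phenotype before screening;
  marker columns are centered as part of standardization.
* **Prediction for unseen samples.** The whitening transform is an
  `n x n` sample-space map and does not extend to new individuals; worse,
  when the fitted `lambda` is large the whitened response lives on a
  shrunken scale, so a forest trained on it would predict new phenotypes
  off by a scale factor. The pipeline therefore fits a *companion*
  prediction forest on the observed-scale phenotype with raw-standardized
  features of the selected markers (same selected set, same tuned `mtry`);
  `predict()` uses that forest. The whitened forest remains the source of
  the importance ranking.

## Design decisions that were genuinely open

* **Importance convention.** The scaled convention (mean OOB MSE increase
  over trees divided by its standard error) is the default because the
  reference score magnitudes (units of several, with SDs of similar order)
  are only consistent with the scaled statistic; the raw mean increase is
  available via `scaledImportance = FALSE`.
* **Forest engine.** The forest stage is delegated to \pkg{ranger}, a
  single-threaded deterministic fit given a seed, with `min.node.size = 5`
  and no depth limit matching the classical regression defaults. An
  independent cross-check against \pkg{randomForest}'s %IncMSE on a shared
  fixture is part of the test suite.
* **Forest response.** The ranking forest is trained on the *whitened*
  phenotype and whitened features, consistent with feeding the stage-2
  model the stage-1 working data; the observed-scale companion forest
  (above) exists only for prediction. Pearson model-fit summaries are
  unaffected by the choice, being scale invariant.
* **Global, not per-SNP, variance components.** `lambda` is estimated once
  under the null model and reused for the whole transform, rather than
  re-estimated per marker.
* **Cross-validation protocol.** The *entire* pipeline - MAF filter,
  kinship, REML, whitening, LARS, forest - is re-run inside every training
  fold. This is the leakage-free protocol: a test fold's phenotypes can
  influence neither the screen nor the forest that predicts them, and the
  suite asserts this by mangling held-out labels. The alternative
  (screening once on the full data, cross-validating only the forest)
  yields optimistic error estimates; with residual variance 10, any honest
  out-of-fold predictor is bounded below by the noise floor
  `E|e| = sqrt(2 * 10 / pi) ~ 2.52` in MAE, a bound worth keeping in mind
  when comparing against in-sample or leaky protocols.
* **Elimination comparator.** The grouped backward-elimination comparator
  (`runTsrfComparator()`) is a best-effort reconstruction from a prose
  description: consecutive positional groups, global elimination of the
  lowest-scoring `groupSize` variables per round. It is documented as
  approximate and not part of the calibrated acceptance surface.
* **MAPE scale.** `mape()` is the literal fraction-scale mean of
  `|(y - yhat)/y|` (no x100). With a grand mean of 10 and phenotype SD
  around 4.3, occasional near-zero phenotypes make MAPE heavy-tailed;
  it is reported for completeness and used for ordering comparisons.

## Problem sizes used by the shipped studies

The packaged acceptance study (`scripts/acceptance.R` at the repository
root) reproduces the simulation summaries at desk scale: 24 replicates of
the full 199 x 10000 design for the importance-score targets and in-sample
fit, 2 replicates of seeded ten-fold cross-validation for the two-stage
pipeline and 1 for the single-stage forest baseline (the baseline refits a
10,000-variable forest per fold, by far the most expensive step). The unit
and property suites run on 20-200-sample instances with a few hundred
markers, sizes at which every oracle can be recomputed from scratch in
seconds.

## Known limitations

* Independent simulated genotypes (no LD), as discussed above: score
  magnitudes on real panels will differ, orderings are the robust output.
* The whitening-based prediction for unseen samples ignores the
  relatedness between new and training individuals (no BLUP-style kinship
  regression); for the prioritization task - the package's purpose -
  prediction is a secondary diagnostic.
* One global `lambda`; traits with strong major loci violate the null
  model under which it is estimated, which biases `lambda` upward and
  makes the whitening mildly conservative.
* `{0,1}`-coded inbred panels and `{0,1,2}` dosages are supported; phased
  or heterozygous-aware codings are not.
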