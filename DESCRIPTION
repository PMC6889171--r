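Package: tslrf
Title: Two-Stage SNP Prioritization with Least Angle Regression and Random
    Forests
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage prioritization of single-nucleotide polymorphisms
    (SNPs) for quantitative traits in structured populations. The phenotype
    is first whitened against polygenic background and population structure
    using a kinship matrix and restricted-maximum-likelihood variance
    components; up to n-1 candidate SNPs are then screened with Least Angle
    Regression; finally the screened subset is ranked by random-forest
    out-of-bag permutation importance (%IncMSE). Includes a heritability-
    calibrated quantitative-trait-nucleotide simulator, single-stage
    random-forest and iterative-elimination comparators, and ten-fold
    cross-validation accuracy metrics (MAE, MAPE, Pearson r).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
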