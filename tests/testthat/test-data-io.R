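test_that("delimited genotype files round-trip, including missing calls", {
  vals <- matrix(c(0, 1, 0, 1, 1, 0), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  g <- GenotypeMatrix(vals,
                      markers = data.frame(id = c("m1", "m2"),
                                           chrom = c("1", "2"),
                                           pos = c(100L, 50L)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(g, f)
  g2 <- readGenotypes(f, "delimited")
  expect_identical_genotypes(g, g2)
  expect_false(any(missingMask(g2)))

  vals[2, 1] <- NA
  gm <- GenotypeMatrix(vals)
  writeGenotypes(gm, f)
  g3 <- readGenotypes(f, "delimited")
  expect_true(missingMask(g3)[2, 1])
  expect_equal(sum(missingMask(g3)), 1L)
})

test_that("simulator output survives a write/read round trip", {
  g <- simulateGenotypes(n = 199, p = 400, seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(g, f)
  expect_identical_genotypes(g, readGenotypes(f, "delimited"))
})

test_that("malformed genotype files raise informative format errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tm1\tm2", "a\t0\t1", "b\t0"), f)
  expect_error(readGenotypes(f, "delimited"), "inconsistent row lengths")
  writeLines(c("sample_id\tm1\tm2", "a\t0\tX", "b\t0\t1"), f)
  expect_error(readGenotypes(f, "delimited"), "unknown genotype symbol 'X'.*m2")
  expect_error(readGenotypes("/nonexistent/geno.tsv", "delimited"),
               "cannot read")
})

test_that("PLINK-style raw dosage files are parsed", {
  f <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snpA snpB snpC",
               "f1 i1 0 0 1 -9 0 1 2",
               "f2 i2 0 0 2 -9 2 NA 0"), f)
  g <- readGenotypes(f, "plink_raw")
  expect_equal(dim(genotypes(g)), c(2L, 3L))
  expect_equal(sampleIds(g), c("i1", "i2"))
  expect_equal(unname(genotypes(g)[1, ]), c(0, 1, 2))
  expect_true(missingMask(g)[2, 2])
  expect_equal(g@codeMax, 2L)
})

test_that("VCF genotypes are read and multi-allelic sites skipped", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "2\t50\trs3\tG\tA\t.\tPASS\t.\tGT\t0|0\t./.\t1|0"), f)
  expect_warning(g <- readGenotypes(f, "vcf"), "multi-allelic")
  expect_equal(nMarkers(g), 2L)
  expect_equal(markerIds(g), c("rs1", "rs3"))
  expect_equal(unname(genotypes(g)[, "rs1"]), c(0, 1, 2))
  expect_true(missingMask(g)["s2", "rs3"])
})

test_that("MAF filtering matches a brute-force allele count", {
  g4 <- GenotypeMatrix(matrix(c(0, 0, 0, 1), 4, 1,
                              dimnames = list(paste0("s", 1:4), "m1")))
  expect_equal(unname(mafValues(g4)), 0.25)
  expect_equal(nMarkers(filterMaf(g4, 0.10)), 1L)
  expect_equal(nMarkers(filterMaf(g4, 0.30)), 0L)

  g <- toyGenotypes(20, 50, seed = 5, missingRate = 0.1)
  vals <- genotypes(g)
  vals[missingMask(g)] <- NA
  brute <- apply(vals, 2, function(col) {
    f <- sum(col, na.rm = TRUE) / sum(!is.na(col))
    min(f, 1 - f)
  })
  expect_equal(unname(mafValues(g)), unname(brute))

  thr <- 0.2
  once <- filterMaf(g, thr)
  expect_equal(markerIds(once), markerIds(g)[brute >= thr])
  expect_identical_genotypes(filterMaf(once, thr), once)  # idempotent
  expect_identical_genotypes(filterMaf(g, 0), g)
})

test_that("markers with all calls missing are excluded with a warning", {
  vals <- matrix(c(NA, NA, NA, 0, 1, 0), 3, 2,
                 dimnames = list(paste0("s", 1:3), c("bad", "ok")))
  g <- GenotypeMatrix(vals)
  expect_warning(out <- filterMaf(g, 0.1), "all calls missing")
  expect_equal(markerIds(out), "ok")
})

test_that("MAF 0.10 filter keeps nearly all markers simulated at frequency 0.30", {
  g <- simulateGenotypes(n = 199, p = 2000, maf = 0.30, seed = 3)
  kept <- nMarkers(filterMaf(g, 0.10)) / nMarkers(g)
  # binomial tail: P(minor count < 20 | Bin(199, 0.3)) is ~1e-9 per marker
  expect_gte(kept, 0.99)
})

test_that("imputation fills missing calls by column mean or major code", {
  vals <- matrix(c(0, 1, NA, 0, 0, 1, NA, 1), 4, 2,
                 dimnames = list(paste0("s", 1:4), c("m1", "m2")))
  g <- GenotypeMatrix(vals)
  gm <- imputeMissing(g, "column_mean")
  expect_false(any(missingMask(gm)))
  expect_equal(genotypes(gm)[3, 1], mean(c(0, 1, 0)))
  gj <- imputeMissing(g, "column_major")
  expect_equal(genotypes(gj)[3, 1], 0)

  gc <- toyGenotypes(5, 4, seed = 2)
  expect_identical_genotypes(imputeMissing(gc, "column_mean"), gc)

  allNA <- GenotypeMatrix(matrix(NA_real_, 3, 1,
                                 dimnames = list(paste0("s", 1:3), "m1")))
  expect_error(imputeMissing(allNA), "filterMaf")
})

test_that("importance tables rank deterministically and round-trip", {
  scores <- c(b = 2.5, a = 2.5, c = 7.1, d = NA)
  markers <- data.frame(id = c("a", "b", "c", "d"), chrom = "1",
                        pos = 1:4, stringsAsFactors = FALSE)
  t <- makeImportanceTable(scores, markers)
  tb <- importanceTable(t)
  expect_equal(tb$marker_id[which(tb$rank == 1)], "c")
  # tie between a and b resolves by input order: b first
  expect_equal(tb$marker_id[match(c(2L, 3L), tb$rank)], c("b", "a"))
  expect_true(is.na(tb$score[tb$marker_id == "d"]))

  f <- withr::local_tempfile(fileext = ".tsv")
  writeImportanceTable(t, f)
  expect_length(readLines(f), 5L)  # header + 4 rows
  t2 <- readImportanceTable(f)
  expect_equal(importanceTable(t2), tb)

  empty <- makeImportanceTable(setNames(numeric(0), character(0)), markers)
  writeImportanceTable(empty, f)
  expect_equal(readLines(f),
               "marker_id\tchromosome\tposition\tscore\trank")
})

test_that("phenotype and kinship files round-trip", {
  y <- setNames(c(10.25, -3, 7.125), c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePhenotypes(y, f)
  expect_equal(readPhenotypes(f), y)

  g <- toyGenotypes(8, 30, seed = 4)
  K <- computeKinship(imputeMissing(g))
  fk <- withr::local_tempfile(fileext = ".tsv")
  writeKinship(K, fk)
  expect_equal(kinshipValues(readKinship(fk)), kinshipValues(K))
})
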