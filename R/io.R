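sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Read a genotype matrix
#'
#' Three formats are supported:
#' \describe{
#'   \item{`delimited`}{first row: marker ids (first cell is a label for the
#'     sample-id column); optional rows labelled `chrom`/`chromosome` and
#'     `pos`/`position` in the first cell; remaining rows: sample id followed
#'     by genotype codes. Tab or comma separated (sniffed).}
#'   \item{`plink_raw`}{PLINK-style `.raw` export: header
#'     `FID IID PAT MAT SEX PHENOTYPE` followed by one 0/1/2 dosage column
#'     per SNP; `NA` marks missing.}
#'   \item{`vcf`}{VCF 4.x with GT calls; multi-allelic sites are skipped with
#'     a warning; needs the \pkg{vcfR} package.}
#' }
#' Cells equal to `NA` or empty are treated as missing. Any other
#' non-numeric symbol is a format error naming the offending cell.
#'
#' @param path file path.
#' @param format one of `"delimited"`, `"plink_raw"`, `"vcf"`.
#' @param codeMax dosage ceiling for the delimited format (1 inbred, 2
#'   dosage); `plink_raw` and `vcf` always use 2.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("delimited", "plink_raw", "vcf"),
                          codeMax = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genotype file: ", path)
  switch(format,
    delimited = readGenotypesDelim(path, codeMax),
    plink_raw = readGenotypesRaw(path),
    vcf = readGenotypesVcf(path)
  )
}

parseCodes <- function(chars, rowIds, colIds, codeMax, path) {
  miss <- is.na(chars) | chars == "NA" | chars == ""
  vals <- suppressWarnings(as.numeric(chars))
  bad <- which(!miss & is.na(vals))
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf("unknown genotype symbol '%s' at sample '%s', marker '%s' in %s",
                 chars[b], rowIds[(b - 1) %% length(rowIds) + 1],
                 colIds[(b - 1) %/% length(rowIds) + 1], path))
  }
  vals[miss] <- NA_real_
  ok <- is.na(vals) | (vals >= 0 & vals <= codeMax)
  if (!all(ok)) {
    b <- which(!ok)[1]
    stop(sprintf("genotype code %s out of range at sample '%s', marker '%s' in %s",
                 vals[b], rowIds[(b - 1) %% length(rowIds) + 1],
                 colIds[(b - 1) %/% length(rowIds) + 1], path))
  }
  vals
}

readGenotypesDelim <- function(path, codeMax) {
  sep <- sniffSep(path)
  lines <- readLines(path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(cells)
  if (length(unique(lens)) != 1L) {
    stop("inconsistent row lengths in ", path)
  }
  ids <- cells[[1]][-1]
  meta <- list(chrom = NULL, pos = NULL)
  rowAt <- 2L
  while (rowAt <= length(cells)) {
    lab <- tolower(cells[[rowAt]][1])
    if (lab %in% c("chrom", "chromosome", "chr")) {
      meta$chrom <- cells[[rowAt]][-1]
    } else if (lab %in% c("pos", "position", "bp")) {
      meta$pos <- as.integer(cells[[rowAt]][-1])
    } else break
    rowAt <- rowAt + 1L
  }
  body <- cells[seq(rowAt, length(cells))]
  samples <- vapply(body, `[`, "", 1L)
  raw <- t(vapply(body, function(x) x[-1], character(length(ids))))
  if (length(ids) == 1L) raw <- matrix(raw, ncol = 1L)
  vals <- matrix(parseCodes(as.vector(raw), samples, ids, codeMax, path),
                 nrow = length(samples))
  dimnames(vals) <- list(samples, ids)
  markers <- data.frame(
    id = ids,
    chrom = if (is.null(meta$chrom)) "1" else meta$chrom,
    pos = if (is.null(meta$pos)) seq_along(ids) else meta$pos,
    stringsAsFactors = FALSE
  )
  GenotypeMatrix(vals, markers = markers, codeMax = codeMax)
}

readGenotypesRaw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(lead %in% names(tab)[seq_along(lead)])) {
    stop("not a PLINK-style raw file (expected header FID IID PAT MAT SEX PHENOTYPE): ",
         path)
  }
  snpCols <- setdiff(names(tab), lead)
  vals <- as.matrix(tab[, snpCols, drop = FALSE])
  if (!is.numeric(vals)) {
    vals <- matrix(parseCodes(as.vector(as.character(vals)), tab$IID, snpCols,
                              2L, path), nrow = nrow(tab))
  }
  dimnames(vals) <- list(tab$IID, snpCols)
  GenotypeMatrix(vals, markers = data.frame(id = snpCols, chrom = "1",
                                            pos = seq_along(snpCols),
                                            stringsAsFactors = FALSE),
                 codeMax = 2L)
}

readGenotypesVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic or ALT-less site(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dose <- function(x) {
    x <- gsub("\\|", "/", x)
    ifelse(is.na(x) | x == "./.", NA_real_,
           vapply(strsplit(x, "/", fixed = TRUE),
                  function(a) sum(as.numeric(a)), 0))
  }
  vals <- t(apply(gt, 1, dose))
  if (ncol(gt) == 1L) vals <- matrix(vals, ncol = 1L)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  vals <- t(vals)
  dimnames(vals) <- list(colnames(gt), ids)
  GenotypeMatrix(vals,
                 markers = data.frame(id = ids, chrom = fix[, "CHROM"],
                                      pos = as.integer(fix[, "POS"]),
                                      stringsAsFactors = FALSE),
                 codeMax = 2L)
}

#' Write a genotype matrix in the delimited format
#'
#' Inverse of `readGenotypes(format = "delimited")`: marker ids, chromosome
#' and position header rows, then one row per sample. Missing calls are
#' written as `NA`.
#'
#' @param g a GenotypeMatrix.
#' @param path output path.
#' @param sep field separator (tab default).
#' @export
writeGenotypes <- function(g, path, sep = "\t") {
  stopifnot(is(g, "GenotypeMatrix"))
  vals <- g@genotypes
  vals[g@missing] <- NA
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE, scientific = FALSE))
  lines <- c(
    paste(c("sample_id", g@markers$id), collapse = sep),
    paste(c("chrom", g@markers$chrom), collapse = sep),
    paste(c("pos", g@markers$pos), collapse = sep),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(rownames(vals)[i], fmt(vals[i, ])), collapse = sep)
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column delimited file (tab or comma, sniffed): sample id and numeric
#' phenotype value; a header row is detected and skipped. `NA` marks missing.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("cannot read phenotype file: ", path)
  sep <- sniffSep(path)
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab[1, 2]))) &&
      !is.na(tab[1, 2])) {
    tab <- tab[-1, , drop = FALSE]
  }
  y <- suppressWarnings(as.numeric(tab[, 2]))
  stats::setNames(y, as.character(tab[, 1]))
}

#' Write a phenotype table
#' @param y named numeric vector.
#' @param path output path.
#' @export
writePhenotypes <- function(y, path) {
  writeLines(c("sample_id\tvalue",
               paste(names(y), format(y, trim = TRUE, digits = 15), sep = "\t")),
             path)
  invisible(path)
}

#' Read a kinship matrix
#'
#' Square tab- or comma-delimited matrix with sample ids as first row and
#' first column; symmetry is validated on read.
#'
#' @param path file path.
#' @return a [KinshipMatrix-class].
#' @export
readKinship <- function(path) {
  if (!file.exists(path)) stop("cannot read kinship file: ", path)
  sep <- sniffSep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  K <- as.matrix(tab)
  if (!identical(rownames(K), colnames(K))) {
    stop("kinship row and column sample ids disagree")
  }
  new("KinshipMatrix", values = K)
}

#' Write a kinship matrix
#' @param k a KinshipMatrix.
#' @param path output path.
#' @export
writeKinship <- function(k, path) {
  K <- k@values
  lines <- c(paste(c("sample_id", colnames(K)), collapse = "\t"),
             vapply(seq_len(nrow(K)), function(i) {
               paste(c(rownames(K)[i], format(K[i, ], digits = 15, trim = TRUE)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked importance table
#'
#' Tab-delimited with header `marker_id  chromosome  position  score  rank`.
#' Unselected markers (missing score) are written with `NA` score and rank.
#'
#' @param t an ImportanceTable.
#' @param path output path.
#' @export
writeImportanceTable <- function(t, path) {
  stopifnot(is(t, "ImportanceTable"))
  tb <- t@table
  lines <- c(paste(c("marker_id", "chromosome", "position", "score", "rank"),
                   collapse = "\t"))
  if (nrow(tb)) {
    lines <- c(lines, vapply(seq_len(nrow(tb)), function(i) {
      paste(c(tb$marker_id[i], tb$chromosome[i], tb$position[i],
              ifelse(is.na(tb$score[i]), "NA",
                     format(tb$score[i], digits = 15, trim = TRUE)),
              ifelse(is.na(tb$rank[i]), "NA", tb$rank[i])), collapse = "\t")
    }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an importance table written by [writeImportanceTable()]
#' @param path file path.
#' @return an [ImportanceTable-class].
#' @export
readImportanceTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer",
                                          "numeric", "integer"))
  names(tab) <- c("marker_id", "chromosome", "position", "score", "rank")
  new("ImportanceTable", table = tab)
}
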