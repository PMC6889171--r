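#' Construct a GenotypeMatrix
#'
#' @param values numeric matrix, samples in rows and markers in columns.
#'   Entries outside the code set are allowed only where missing.
#' @param sampleIds character vector of sample identifiers (defaults to the
#'   rownames of `values`).
#' @param markers data.frame with columns `id`, `chrom`, `pos`; defaults to
#'   colnames of `values` on a single unnamed chromosome.
#' @param missing logical matrix flagging missing calls; defaults to
#'   `is.na(values)`.
#' @param codeMax 1 for inbred `{0,1}` coding, 2 for `{0,1,2}` dosages.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 0, 1, 1, 0), 3, 2,
#'                            dimnames = list(paste0("s", 1:3), c("m1", "m2"))))
#' nSamples(g)
#' @export
GenotypeMatrix <- function(values, sampleIds = rownames(values),
                           markers = NULL, missing = NULL, codeMax = 1L) {
  values <- as.matrix(values)
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("marker", seq_len(ncol(values)))
  rownames(values) <- sampleIds
  if (is.null(markers)) {
    markers <- data.frame(id = colnames(values), chrom = "1",
                          pos = seq_len(ncol(values)), stringsAsFactors = FALSE)
  }
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  colnames(values) <- markers$id
  if (is.null(missing)) missing <- is.na(values)
  dimnames(missing) <- dimnames(values)
  new("GenotypeMatrix", genotypes = values, markers = markers,
      missing = missing, codeMax = as.integer(codeMax))
}

#' @rdname GenotypeMatrix-class
#' @aliases nSamples,GenotypeMatrix-method
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@genotypes))

#' @rdname GenotypeMatrix-class
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@genotypes))

#' @rdname GenotypeMatrix-class
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@genotypes))

#' @rdname GenotypeMatrix-class
setMethod("markerIds", "GenotypeMatrix", function(x) x@markers$id)

#' @rdname GenotypeMatrix-class
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markers)

#' @rdname GenotypeMatrix-class
setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)

#' @rdname GenotypeMatrix-class
setMethod("missingMask", "GenotypeMatrix", function(x) x@missing)

#' @rdname mafValues
setMethod("mafValues", "GenotypeMatrix", function(x) {
  g <- x@genotypes
  g[x@missing] <- NA_real_
  nObs <- colSums(!is.na(g))
  freq <- colSums(g, na.rm = TRUE) / (nObs * x@codeMax)
  maf <- pmin(freq, 1 - freq)
  maf[nObs == 0] <- NA_real_
  stats::setNames(maf, x@markers$id)
})

#' Subset samples and/or markers of a GenotypeMatrix
#'
#' @param x a GenotypeMatrix.
#' @param i sample index (integer, logical or sample id).
#' @param j marker index (integer, logical or marker id).
#' @param ... ignored.
#' @param drop ignored; the result is always a GenotypeMatrix.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  if (is.character(j)) j <- match(j, x@markers$id)
  jl <- seq_len(ncol(x@genotypes))[j]
  new("GenotypeMatrix",
      genotypes = x@genotypes[i, jl, drop = FALSE],
      markers = x@markers[jl, , drop = FALSE],
      missing = x@missing[i, jl, drop = FALSE],
      codeMax = x@codeMax)
})

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d markers (codes 0..%d)\n",
              nSamples(object), nMarkers(object), object@codeMax))
  chroms <- unique(object@markers$chrom)
  cat(sprintf("  chromosomes: %s\n",
              paste(utils::head(chroms, 6), collapse = ", ")))
  nm <- sum(object@missing)
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              100 * nm / max(1, length(object@missing))))
})

#' Filter markers by minor allele frequency
#'
#' Drops markers whose minor-allele frequency, computed over non-missing
#' calls, is below `threshold`. Markers with no observed calls are excluded
#' with a warning. Sample set and marker order are preserved.
#'
#' @param g a GenotypeMatrix.
#' @param threshold MAF threshold in `[0, 0.5]`; markers with MAF >=
#'   `threshold` are kept. Default 0.10.
#' @return the filtered GenotypeMatrix.
#' @export
filterMaf <- function(g, threshold = 0.10) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (threshold < 0 || threshold > 0.5) {
    stop("MAF threshold must lie in [0, 0.5]")
  }
  maf <- mafValues(g)
  allMissing <- is.na(maf)
  if (any(allMissing)) {
    warning(sprintf("excluding %d marker(s) with all calls missing",
                    sum(allMissing)))
  }
  keep <- !allMissing & maf >= threshold
  g[, keep]
}

#' Impute missing genotype calls
#'
#' @param g a GenotypeMatrix.
#' @param strategy `"column_mean"` replaces missing calls with the column
#'   mean of observed codes (non-integer values allowed); `"column_major"`
#'   uses the most frequent observed code (smallest code on ties).
#' @return a GenotypeMatrix with an all-FALSE missing mask.
#' @export
imputeMissing <- function(g, strategy = c("column_mean", "column_major")) {
  stopifnot(is(g, "GenotypeMatrix"))
  strategy <- match.arg(strategy)
  vals <- g@genotypes
  miss <- g@missing
  if (!any(miss)) {
    g@missing[] <- FALSE
    return(g)
  }
  bad <- colSums(!miss) == 0
  if (any(bad)) {
    stop(sprintf("%d column(s) are fully missing; run filterMaf() first",
                 sum(bad)))
  }
  for (j in which(colSums(miss) > 0)) {
    obs <- vals[!miss[, j], j]
    fill <- if (strategy == "column_mean") {
      mean(obs)
    } else {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])
    }
    vals[miss[, j], j] <- fill
  }
  new("GenotypeMatrix", genotypes = vals, markers = g@markers,
      missing = array(FALSE, dim(vals), dimnames = dimnames(vals)),
      codeMax = g@codeMax)
}
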