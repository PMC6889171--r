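#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' Minor allele frequency per marker
#'
#' Computed over non-missing calls only; the denominator is the number of
#' non-missing calls times the dosage ceiling (`codeMax`).
#'
#' @param x a GenotypeMatrix.
#' @return named numeric vector of per-marker minor-allele frequencies.
#' @export
setGeneric("mafValues", function(x) standardGeneric("mafValues"))

#' @rdname KinshipMatrix-class
#' @export
setGeneric("kinshipValues", function(x) standardGeneric("kinshipValues"))

#' @rdname ImportanceTable-class
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))
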