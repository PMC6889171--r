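#' Build a ranked ImportanceTable from scores and marker metadata
#'
#' Rank 1 is the largest score; ties are broken deterministically by marker
#' order (first marker wins). Markers without a score (e.g. not selected by
#' the screening stage) get `NA` score and rank when included.
#'
#' @param scores named numeric vector of %IncMSE scores; names are marker ids.
#' @param markers data.frame with columns `id`, `chrom`, `pos` covering at
#'   least the scored markers.
#' @return an [ImportanceTable-class], rows sorted by rank (scored markers
#'   first), unscored markers after in marker order.
#' @export
makeImportanceTable <- function(scores, markers) {
  idx <- match(names(scores), markers$id)
  if (anyNA(idx)) stop("scores name markers absent from metadata")
  tb <- data.frame(
    marker_id = names(scores),
    chromosome = markers$chrom[idx],
    position = markers$pos[idx],
    score = as.numeric(scores),
    stringsAsFactors = FALSE
  )
  scored <- !is.na(tb$score)
  rk <- rep(NA_integer_, nrow(tb))
  # order(order(...)) maps each row to its rank; ties fall back to input order
  rk[scored] <- order(order(-tb$score[scored], seq_len(sum(scored))))
  tb$rank <- rk
  tb <- tb[order(is.na(tb$score), tb$rank), , drop = FALSE]
  rownames(tb) <- NULL
  new("ImportanceTable", table = tb)
}

#' @rdname ImportanceTable-class
setMethod("importanceTable", "ImportanceTable", function(x) x@table)

#' @rdname ImportanceTable-class
setMethod("importanceTable", "TslrfResult", function(x) x@importance@table)

#' Coerce an ImportanceTable to data.frame
#' @param x an ImportanceTable.
#' @param ... ignored.
#' @export
as.data.frame.ImportanceTable <- function(x, ...) x@table

setMethod("show", "ImportanceTable", function(object) {
  tb <- object@table
  cat(sprintf("ImportanceTable: %d markers (%d scored)\n",
              nrow(tb), sum(!is.na(tb$score))))
  print(utils::head(tb, 5))
  if (nrow(tb) > 5) cat("  ...\n")
})

#' Top-ranked rows of an importance table
#'
#' @param x an ImportanceTable or TslrfResult.
#' @param m number of rows to report (default 20).
#' @return data.frame of the `m` best-ranked scored markers.
#' @export
topMarkers <- function(x, m = 20) {
  tb <- importanceTable(x)
  tb <- tb[!is.na(tb$rank), , drop = FALSE]
  utils::head(tb[order(tb$rank), , drop = FALSE], m)
}
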