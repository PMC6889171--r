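# stage-tagged progress log to stderr; silent unless options(tslrf.verbose)
stageLog <- function(stage, fmt, ...) {
  if (isTRUE(getOption("tslrf.verbose"))) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic derivation of per-stage / per-replicate seeds from one
#' master seed, so that partial reruns are reproducible. The tag string is
#' hashed with a small multiplicative scheme and folded with the master
#' seed; results always lie in `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the stage or replicate (e.g. `"lars"`,
#'   `"rep12"`).
#' @return a positive integer seed.
#' @export
deriveSeed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  val <- (as.numeric(seed) * 48271 + h * 16807) %% 2147483646
  as.integer(val + 1)
}
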