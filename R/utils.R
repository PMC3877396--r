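#' @useDynLib mklconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rnorm runif sd var pt qt p.adjust prcomp quantile
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stages of the pipeline draw their random numbers from seeds derived
#' deterministically from one global seed and the stage name, so a stage can
#' be rerun in isolation and reproduce the full-pipeline result.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003L) * 2017L + (h %% 999983L)) %% 2147483646L
}

## Lightweight run log: operations append condition notes (zero-variance
## voxels zeroed, ridge repairs, capped ratios, ...) that callers can inspect.
log_note <- function(x, note) {
  attr(x, "log") <- c(attr(x, "log"), note)
  x
}

#' Retrieve processing notes attached to a result
#' @param x an object returned by a pipeline operation.
#' @return character vector of notes (possibly empty).
#' @export
run_log <- function(x) attr(x, "log") %||% character(0)

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (anyNA(x)) stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  invisible(x)
}
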