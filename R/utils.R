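#' @useDynLib reactionet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats splinefun rbinom rpois sd var quantile setNames
#' @importFrom utils combn head tail
NULL

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Expands one master seed deterministically into independent per-stage
#' seeds (simulation, noise, bootstrap, cross-validation, ...), so stages
#' can be re-run in isolation. Derived seeds stay below 2^31.
#'
#' @param master integer master seed.
#' @param label stage label, e.g. `"bootstrap"`.
#' @param index optional integer sub-index (replicate number, fold, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(master, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  s <- (as.numeric(master) %% 2147483647) * 31 + h * 1009 + as.numeric(index) * 7919
  as.integer(s %% 2147483629) + 1L
}

rn_log <- function(fmt, ..., verbose = TRUE, logfile = NULL) {
  if (!verbose && is.null(logfile)) return(invisible(NULL))
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  if (verbose) message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(NULL)
}
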