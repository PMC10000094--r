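#' @keywords internal
#' @useDynLib trapslim, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Derive a reproducible sub-seed
#'
#' Folds a run of integers into a single seed below 2^31, so independent
#' stages (sites, draws, pipeline steps) get decoupled but fully
#' reproducible RNG streams from one master seed.
#'
#' @param seed master seed.
#' @param ... further integers identifying the stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  s <- 0
  for (k in ks) s <- (s * 69069 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  as.integer(s)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, evaluates \code{expr}, and restores the caller's
#' RNG state afterwards.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round() in R is round-half-even; pruned channel counts use half-up so that
# e.g. ratio 0.5 of 3 channels keeps 2, never 1 by parity accident.
round_half_up <- function(x) floor(x + 0.5)

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
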