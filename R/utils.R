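#' Derive a child RNG seed from a base seed and a stream label
#'
#' All stochastic stages (variant generation, genotypes, phenotypes, fold
#' assignment, parameter initialisation, restarts) draw their seeds through
#' this helper so that a single integer reproduces an entire analysis while
#' stages stay statistically independent.
#'
#' @param seed base integer seed
#' @param ... labels (coerced to character) identifying the stream
#' @return an integer seed in `[0, 2^31 - 1)`
#' @keywords internal
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1
  h <- 17
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

`%||%` <- rlang::`%||%`
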