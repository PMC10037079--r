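#' Derive a named RNG substream seed
#'
#' All randomised operations in the package fork a named substream off a
#' single user-visible seed, so that e.g. adding false positives to a caller
#' profile does not shift the genotype draws of the truth set.  The derived
#' seed is a deterministic 31-bit hash of \code{(seed, name)}.
#'
#' @param seed integer master seed.
#' @param name character substream label.
#' @return an integer seed in \code{[0, 2^31)}.
#' @keywords internal
substreamSeed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(name) == 1L)
  h <- 0
  for (cc in utf8ToInt(as.character(name))) {
    h <- (h * 131 + cc) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

#' Evaluate code under a named RNG substream
#'
#' @param seed integer master seed.
#' @param name character substream label.
#' @param code code to evaluate.
#' @keywords internal
withSubstream <- function(seed, name, code) {
  withr::with_seed(substreamSeed(seed, name), code)
}
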