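#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single master seed.  Components
#' (genotype simulation, expression noise, per-exon permutation streams,
#' resampling) each receive a child seed derived deterministically from the
#' master seed and a stream index, so that any stage can be reproduced in
#' isolation.
#'
#' @param seed master seed (integer).
#' @param stream non-negative integer stream index; vectors are allowed.
#' @return integer seed(s) in [1, 2^31 - 2].
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(stream), all(stream >= 0))
  # multiplicative congruential mix; modulus is the Mersenne prime 2^31 - 1
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  out <- (x * 48271 + as.numeric(stream) * 16807 + 1) %% m
  as.integer(out %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
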