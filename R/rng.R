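#' Derive a child seed from a master seed
#'
#' Counter-based seed derivation: subject k of a cohort (or replicate r of a
#' power run) is simulated from `child_seed(master, k)`, so any subset of
#' subjects or replicates can be reproduced independently of the rest. The
#' mixing is a fixed affine-multiplicative hash modulo the Mersenne prime
#' 2^31 - 1; all arithmetic stays below 2^53 so it is exact in doubles.
#'
#' @param seed Master seed (integer-valued).
#' @param index Non-negative counter.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  x <- (x * 48271 + as.numeric(index) * 16807 + 104729) %% m
  x <- (x * 69621) %% m
  if (x == 0) x <- 1
  as.integer(x)
}
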