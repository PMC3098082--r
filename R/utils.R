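#' @keywords internal
"_PACKAGE"

# Deterministic seed derivation. Replicate/worker seeds are pure functions of
# (parent seed, index), so serial and parallel schedules see identical streams.
# Constants are the classic Lehmer/minstd multipliers; all arithmetic stays
# below 2^31 via the 2147483647 modulus.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  m <- 2147483647
  s <- (as.double(seed) %% m)
  x <- (s * 48271 + (as.double(index) + 1) * 16807 + 12345) %% m
  # avoid the fixed point 0
  as.integer(if (x == 0) 1 else x)
}

# Shannon entropy (bits) of a vector of class labels.
entropy_bits <- function(labels) {
  n <- length(labels)
  if (n == 0L) return(0)
  p <- tabulate(as.integer(labels))
  p <- p[p > 0] / n
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
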