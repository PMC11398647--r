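#' Derive a child RNG seed from a master seed and a tag
#'
#' All randomness in the package flows from integer seeds, so that every
#' corpus, network and trial is a pure function of a single master seed.
#' Child seeds are produced by chaining a Lehmer-style congruential mix of the
#' master seed with the integer/character components of a tag; all arithmetic
#' stays below 2^53 so it is exact in doubles, and the result is in
#' [1, 2^31 - 2].
#'
#' @param seed master seed (non-negative integer).
#' @param ... tag components (integers or character scalars) identifying the
#'   consumer, e.g. `derive_seed(s, "trial", 7)`.
#' @return an integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  a <- 48271
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      codes <- utf8ToInt(paste(part, collapse = "/"))
    } else {
      codes <- as.numeric(part)
    }
    for (cd in codes) {
      h <- (a * h + (cd %% m) + 1) %% m
    }
  }
  # one extra scramble round so short tags do not map near-identity
  h <- (a * h + 12345) %% m
  as.integer(h %% (m - 1)) + 1L
}
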