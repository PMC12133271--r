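#' Derive a reproducible child seed from a root seed
#'
#' Deterministically mixes a root seed with one or more stream indices
#' (scenario number, replicate number, ...) into a new seed in
#' `[0, 2^31 - 2]`. Used throughout the simulation orchestrator so that
#' every scenario and every replicate owns an independent, reproducible
#' random stream: replicates can be executed in any order, or in parallel,
#' without changing results.
#'
#' The mixer is a multiply-with-carry style congruential hash modulo the
#' Mersenne prime 2^31 - 1; all intermediate products stay below 2^53 so
#' the arithmetic is exact in doubles.
#'
#' @param root integer root seed.
#' @param ... integer stream indices, applied in order.
#' @return a single integer seed suitable for [set.seed()].
#' @examples
#' derive_seed(1, 3, 17)
#' derive_seed(1, 3, 18) # differs
#' @export
derive_seed <- function(root, ...) {
  idx <- c(...)
  h <- abs(as.double(root)) %% 2147483647
  for (v in idx) {
    h <- (h * 69069 + abs(as.double(v)) + 1) %% 2147483647
  }
  # one extra stir so derive_seed(r) != r
  h <- (h * 69069 + 1) %% 2147483647
  as.integer(h)
}
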