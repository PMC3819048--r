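`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a global seed
#'
#' Deterministic counter-based fan-out used so that pipeline stages, runs and
#' replications can be re-seeded independently yet reproducibly from one
#' global seed.  Keys are folded in with a Lehmer-style multiplicative step
#' modulo the Mersenne prime 2^31 - 1, so every derived seed is a valid
#' 32-bit R integer.
#'
#' @param seed integer global seed.
#' @param ... integer keys (stage index, run index, ...), folded in order.
#' @return a single integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  x <- (as.numeric(seed) %% m)
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(x + 1)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# half-open [a, b) sample index range for a time interval (ms) on a grid
# where sample s covers time [s/fs, (s+1)/fs); endpoints floored to the grid
ms_to_samples <- function(interval_ms, fs_hz, window_ms) {
  i0 <- floor((interval_ms[1] - window_ms[1]) * fs_hz / 1000) + 1
  i1 <- floor((interval_ms[2] - window_ms[1]) * fs_hz / 1000)
  c(max(1L, as.integer(i0)), as.integer(i1))
}
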