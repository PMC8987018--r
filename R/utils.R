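# Internal condition helpers and seed derivation shared across modules.

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("pyroscore_data_error", "pyroscore_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("pyroscore_config_error", "pyroscore_error")))
}

#' Derive a stage seed from a global seed
#'
#' Stage seeds are a deterministic function of the global pipeline seed and a
#' stage counter, so every stochastic stage is individually reproducible from
#' one integer. The result always fits a 32-bit R integer.
#'
#' @param seed Global integer seed.
#' @param offset Stage counter (small non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 1009 + offset * 9973) %% 2147483647)
}
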