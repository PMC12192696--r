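#' Derive a reproducible child seed
#'
#' Counter-based derivation of independent child seeds from a master seed,
#' so that adding replicates or clusters never perturbs the streams of
#' earlier ones. All randomness in the package flows through explicit
#' seeds derived this way.
#'
#' @param seed master seed (integer-like).
#' @param index non-negative counter distinguishing the child stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  s0 <- as.numeric(seed) %% 2147483647
  i0 <- as.numeric(index) %% 2147483647
  # affine mix; products stay below 2^53 so double arithmetic is exact
  x <- (s0 * 1103 + (i0 %% 1048576) * 7919 + (i0 %/% 1048576) * 104729 + 13) %% 2147483629
  as.integer(x) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
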