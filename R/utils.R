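#' Derive a component seed from a root seed
#'
#' All randomness in the package flows from a single root seed. Component
#' seeds (simulator, fold assignment, learner fits, network initialisation)
#' are derived deterministically from the root via a Lehmer-style multiplier
#' so that independent components never share a stream.
#'
#' @param root integer root seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, stream = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  stopifnot(is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  as.integer(((abs(root) %% m) * 48271 + (stream + 1) * 104729) %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_talsrx <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# round-half-up, used for fractional split sizes
round_half_up <- function(x) floor(x + 0.5)
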