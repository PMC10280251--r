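#' Root-mean-square of a numeric vector
#'
#' @param x Numeric vector.
#' @return Non-negative scalar, `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  stopifnot(is.numeric(x))
  sqrt(mean(x^2))
}

# Evaluate expr under a private RNG stream so generators are pure functions of
# their seed and never disturb the caller's RNG state.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a master seed and a counter, kept inside the 32-bit
# integer range. Deterministic and collision-free for counters < 1e6.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 7919 + as.double(counter) * 104729) %% 2147483629L)
}

abort_bad_arg <- function(name, must) {
  stop(sprintf("`%s` %s", name, must), call. = FALSE)
}

check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_bad_arg(name, "must be a single finite number")
  }
  if (positive && x <= 0) abort_bad_arg(name, "must be positive")
  invisible(x)
}

# Normalise a signal to zero mean and RMS equal to `amplitude`.
# amplitude = 0 (or an all-constant signal) yields exact zeros.
scale_signal <- function(x, amplitude) {
  x <- x - mean(x)
  r <- rms(x)
  if (amplitude == 0 || r == 0) return(rep(0, length(x)))
  x * (amplitude / r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
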