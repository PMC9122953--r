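# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse-logit transform
#'
#' Maps a linear predictor on the logit scale to a mean in (0, 1).
#'
#' @param eta numeric vector.
#' @return numeric vector in (0, 1).
#' @keywords internal
inv_logit <- function(eta) stats::plogis(eta)

## Wilson score interval for a binomial proportion; vectorised over x.
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

## stop() with call.=FALSE and sprintf semantics
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!all(is.finite(x) & lo_ok & hi_ok)) {
    abort("`%s` must lie in %s0, 1%s", name,
          if (open_left) "(" else "[", if (open_right) ")" else "]")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x)) {
    abort("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

## Deterministic derived seed: small offsets keep everything below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
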