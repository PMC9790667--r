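#' @keywords internal
"_PACKAGE"

## Classed conditions used throughout the package. `class` is one of
## "io", "channel", "format", "parameter", "eligibility", "validation",
## "domain", "generation", "estimation".
spa_error <- function(class, message, ...) {
  stop(errorCondition(message,
                      class = c(paste0("spindlespa_", class, "_error"),
                                "spindlespa_error"),
                      ...))
}

assert_that <- function(ok, class, message) {
  if (!isTRUE(ok)) spa_error(class, message)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Derive a reproducible child seed from a master seed. Kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 1103) %% 2147483629)
}

#' Tukey (tapered cosine) window
#'
#' @param n window length in samples.
#' @param alpha fraction of the window inside the cosine ramps (0 = rectangular,
#'   1 = Hann).
#' @return numeric vector of length `n` in `[0, 1]`.
#' @export
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  ramp <- alpha / 2
  lo <- t < ramp
  hi <- t > 1 - ramp
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

## Centered moving average with edge truncation (window shrinks at edges).
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- floor(width / 2)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Runs of TRUE in a logical vector as a two-column matrix [start, end]
## (sample indices, inclusive).
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
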