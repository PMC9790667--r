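## Zero-phase band-pass filtering in the frequency domain.
##
## All filters in the package are realized as real, even-symmetric transfer
## functions applied to the DFT of the (demeaned) signal: exactly zero phase,
## so spindle timing is preserved, at O(n log n) cost. Band edges use
## raised-cosine transitions so passband gain is unity and stopband
## attenuation is complete up to spectral leakage.

## Memoized transfer functions: the same (n, fs, band) combination recurs
## for every channel and subject of a cohort.
.transfer_cache <- new.env(parent = emptyenv())

band_transfer_cached <- function(n, fs, lo_hz, hi_hz, transition_hz) {
  key <- paste(n, fs, lo_hz, hi_hz, transition_hz, sep = "|")
  h <- .transfer_cache[[key]]
  if (is.null(h)) {
    h <- band_transfer(n, fs, lo_hz, hi_hz, transition_hz)
    if (length(.transfer_cache) > 32) {
      rm(list = ls(.transfer_cache), envir = .transfer_cache)
    }
    .transfer_cache[[key]] <- h
  }
  h
}

## Transfer function sampled at the DFT frequencies of an n-point signal.
band_transfer <- function(n, fs, lo_hz, hi_hz, transition_hz = 0.75) {
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  af <- abs(f)
  h <- numeric(n)
  ramp_up <- function(x, a, b) {
    ## 0 below a, raised-cosine to 1 at b
    y <- (x - a) / (b - a)
    y <- pmin(pmax(y, 0), 1)
    0.5 * (1 - cos(pi * y))
  }
  hp <- if (lo_hz > 0) ramp_up(af, lo_hz - transition_hz / 2, lo_hz + transition_hz / 2) else 1
  lp <- 1 - ramp_up(af, hi_hz - transition_hz / 2, hi_hz + transition_hz / 2)
  hp * lp
}

#' Zero-phase band-pass filter
#'
#' Filters a signal with a zero-phase frequency-domain band-pass. The mean is
#' removed before filtering, so any pass band excluding DC rejects constant
#' offsets exactly.
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate in Hz.
#' @param lo_hz,hi_hz pass-band edges in Hz (`lo_hz = 0` gives a low-pass).
#' @param transition_hz total width of the raised-cosine band edges.
#' @return filtered signal, same length as `x`.
#' @export
fft_bandpass <- function(x, fs, lo_hz, hi_hz, transition_hz = 0.75) {
  assert_that(is_number(fs) && fs > 0, "parameter", "fs must be positive")
  assert_that(hi_hz < fs / 2, "parameter",
              sprintf("upper cut-off %.3g Hz is not below Nyquist (%.3g Hz)",
                      hi_hz, fs / 2))
  assert_that(lo_hz < hi_hz, "parameter", "lo_hz must be below hi_hz")
  n <- length(x)
  if (n == 0L) return(x)
  x <- x - mean(x)
  h <- band_transfer_cached(n, fs, lo_hz, hi_hz, transition_hz)
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

## Filter two real channels with one complex FFT round-trip: the transfer
## function is real and even in frequency, so filtering z = x1 + i*x2 keeps
## the two channels in the real and imaginary parts.
fft_bandpass_pair <- function(x1, x2, fs, lo_hz, hi_hz, transition_hz = 0.75) {
  n <- length(x1)
  h <- band_transfer_cached(n, fs, lo_hz, hi_hz, transition_hz)
  z <- stats::fft(stats::fft(complex(real = x1 - mean(x1),
                                     imaginary = x2 - mean(x2))) * h,
                  inverse = TRUE) / n
  list(Re(z), Im(z))
}

## Band-passed analytic signal: one FFT round-trip gives both the zero-phase
## band-passed signal (Re) and its envelope (Mod).
analytic_bandpass <- function(x, fs, lo_hz, hi_hz, transition_hz = 0.75) {
  n <- length(x)
  x <- x - mean(x)
  h <- band_transfer_cached(n, fs, lo_hz, hi_hz, transition_hz)
  ## analytic-signal weights: double positive frequencies, zero negatives
  u <- numeric(n)
  half <- floor(n / 2)
  u[1L] <- 1
  if (n %% 2 == 0) {
    u[2:half] <- 2
    u[half + 1L] <- 1
  } else {
    u[2:(half + 1L)] <- 2
  }
  stats::fft(stats::fft(x) * h * u, inverse = TRUE) / n
}

## Resample to a target rate with anti-aliasing (delegated to signal::resample).
resample_signal <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(x)
  r <- MASS_fractions(fs_to / fs_from)
  signal::resample(x, p = r[1], q = r[2])
}

## Small rational approximation p/q of a ratio.
MASS_fractions <- function(ratio, max_den = 1000L) {
  best <- c(1L, 1L)
  err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    if (p < 1) next
    e <- abs(p / q - ratio)
    if (e < err - 1e-15) {
      best <- c(p, q)
      err <- e
    }
    if (err < 1e-12) break
  }
  as.integer(best)
}
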