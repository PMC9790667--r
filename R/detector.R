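#' Spindle detector parameters
#'
#' Defaults realize a standard sigma-envelope detector: the 11-15 Hz band is
#' extracted with a zero-phase band-pass, the magnitude of the analytic
#' signal is smoothed with a 0.2 s moving average, and spindles are the
#' supra-threshold envelope runs satisfying duration bounds. The relative
#' threshold is computed per derivation over that subject's N2 data, so
#' detection is self-normalizing within each channel; this deliberately
#' avoids pooling across hemispheres, which would bias detection against the
#' low-amplitude (lesioned) side and inflate the asymmetry measure.
#'
#' @param sigma_band spindle band in Hz.
#' @param envelope_smooth_s moving-average width for the envelope, seconds.
#' @param threshold_mode `"mean_plus_k_sd"` (default) or `"percentile"`.
#' @param threshold_value `k` for the mean + k SD rule, or the percentile
#'   (0-100) for percentile mode.
#' @param min_abs_amplitude_uv absolute envelope floor in microvolts.
#' @param min_dur_s,max_dur_s event duration bounds in seconds.
#' @param merge_gap_s supra-threshold runs closer than this are merged.
#' @return object of class `detector_params`.
#' @export
detector_params <- function(sigma_band = c(11, 15),
                            envelope_smooth_s = 0.2,
                            threshold_mode = c("mean_plus_k_sd", "percentile"),
                            threshold_value = 2,
                            min_abs_amplitude_uv = 5,
                            min_dur_s = 0.5,
                            max_dur_s = 3.0,
                            merge_gap_s = 0.25) {
  threshold_mode <- match.arg(threshold_mode)
  assert_that(min_dur_s < max_dur_s, "parameter",
              "min_dur_s must be below max_dur_s")
  assert_that(length(sigma_band) == 2 && sigma_band[1] < sigma_band[2],
              "parameter", "sigma_band must be (lo, hi)")
  structure(list(sigma_band = sigma_band,
                 envelope_smooth_s = envelope_smooth_s,
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_abs_amplitude_uv = min_abs_amplitude_uv,
                 min_dur_s = min_dur_s, max_dur_s = max_dur_s,
                 merge_gap_s = merge_gap_s),
            class = "detector_params")
}

#' Sigma-band filter
#'
#' Zero-phase band-pass restricted to the spindle band.
#'
#' @param x numeric signal in microvolts.
#' @param fs sampling rate in Hz.
#' @param band `c(lo, hi)` in Hz.
#' @return filtered signal, same length.
#' @export
sigma_filter <- function(x, fs, band = c(11, 15)) {
  assert_that(fs >= 2 * band[2] * 1.2, "parameter",
              "sampling rate too low for the requested sigma band")
  fft_bandpass(x, fs, band[1], band[2])
}

#' Sigma envelope
#'
#' Instantaneous amplitude (magnitude of the analytic signal) of the
#' sigma-filtered signal, smoothed with a moving average.
#'
#' @param x sigma-filtered signal (microvolts).
#' @param fs sampling rate in Hz.
#' @param smooth_s moving-average width in seconds (at least two cycles of
#'   the fastest spindle frequency).
#' @return non-negative envelope, same length as `x`.
#' @export
sigma_envelope <- function(x, fs, smooth_s = 0.2) {
  assert_that(smooth_s >= 2 / 15, "parameter",
              "smooth_s must cover at least two spindle cycles (>= 2/15 s)")
  env <- Mod(analytic_bandpass(x, fs, 0, fs / 2 * 0.999, transition_hz = 1e-6))
  moving_average(env, max(1L, round(smooth_s * fs)))
}

#' Classify a spindle by oscillation frequency
#'
#' Slow spindles occupy 11-13 Hz and fast spindles 13-15 Hz; the 13 Hz
#' boundary is assigned upward (fast). Every spindle also belongs to the
#' full band.
#'
#' @param osc_freq_hz oscillation frequency in Hz (vectorized).
#' @return character vector, `"slow"` or `"fast"`.
#' @export
classify_band <- function(osc_freq_hz) {
  assert_that(all(osc_freq_hz >= 11 - 1e-9 & osc_freq_hz <= 15 + 1e-9),
              "parameter", "oscillation frequency outside the 11-15 Hz band")
  ifelse(osc_freq_hz < 13, "slow", "fast")
}

#' Oscillation frequency of one event
#'
#' Location of the power-spectral-density maximum of the (tapered,
#' zero-padded) event within the sigma band, refined to sub-bin resolution by
#' parabolic interpolation. Exact ties are broken to the lower frequency.
#'
#' @param x event samples (sigma-filtered, microvolts).
#' @param fs sampling rate in Hz.
#' @param band search band in Hz.
#' @return frequency in Hz.
#' @export
event_osc_frequency <- function(x, fs, band = c(11, 15)) {
  assert_that(length(x) / fs >= 2 / band[1], "estimation",
              "event shorter than two cycles of the lowest band frequency")
  n <- length(x)
  x <- (x - mean(x)) * tukey_window(n, alpha = 1)  # Hann taper
  nfft <- max(2048L, 2^ceiling(log2(n)))           # 0.125 Hz bins at 256 Hz
  p <- Mod(stats::fft(c(x, numeric(nfft - n))))^2
  f <- (seq_len(nfft) - 1L) * fs / nfft
  sel <- which(f >= band[1] & f <= band[2])
  k <- sel[which.max(p[sel])]                      # first max = lower frequency
  ## parabolic refinement on log-power
  if (k > 1L && k < nfft && p[k - 1L] > 0 && p[k + 1L] > 0) {
    a <- log(p[k - 1L]); b <- log(p[k]); c <- log(p[k + 1L])
    denom <- a - 2 * b + c
    delta <- if (abs(denom) > 1e-12) 0.5 * (a - c) / denom else 0
    delta <- min(max(delta, -0.5), 0.5)
  } else delta <- 0
  min(max(f[k] + delta * fs / nfft, band[1]), band[2])
}

#' Mean power of one event
#'
#' Mean of the squared sigma-filtered signal over the event, in microvolts
#' squared (equivalently the within-band power of the event).
#'
#' @param x event samples (sigma-filtered, microvolts).
#' @param fs sampling rate in Hz (unused; kept for interface symmetry).
#' @return mean power in microvolts squared.
#' @export
event_mean_power <- function(x, fs = NULL) {
  mean(x^2)
}

#' Detect sleep spindles on a bipolar N2 recording
#'
#' Events are maximal runs where the smoothed sigma envelope exceeds both the
#' per-derivation relative threshold and the absolute amplitude floor;
#' supra-threshold runs separated by less than `merge_gap_s` are merged, and
#' events must last between `min_dur_s` and `max_dur_s`. Runs never span N2
#' segment boundaries. Onsets and offsets are reported in original recording
#' time.
#'
#' @param bip a `bipolar_recording` from [extract_n2()].
#' @param params a [detector_params()].
#' @param min_total_s minimum data length per derivation, seconds.
#' @return data frame of class `spindle_events` with columns `subject_id`,
#'   `derivation`, `onset_s`, `offset_s`, `duration_s`, `osc_freq_hz`,
#'   `mean_power_uv2`, `peak_uv`, `band`. The per-derivation thresholds and
#'   event densities are attached as attributes `thresholds` and
#'   `density_per_min`.
#' @export
detect_spindles <- function(bip, params = detector_params(),
                            min_total_s = 300) {
  stopifnot(inherits(bip, "bipolar_recording"))
  fs <- bip$fs
  derivs <- colnames(bip$data)
  n <- nrow(bip$data)
  assert_that(n / fs >= min_total_s, "parameter",
              sprintf("need at least %.0f s of N2 data", min_total_s))
  seg <- bip$segment %||% rep.int(1L, n)
  out <- vector("list", length(derivs))
  thresholds <- stats::setNames(rep(NA_real_, length(derivs)), derivs)
  density <- stats::setNames(rep(NA_real_, length(derivs)), derivs)

  for (d in seq_along(derivs)) {
    name <- derivs[d]
    if (name %in% bip$excluded) next
    x <- bip$data[, d]
    if (all(x == 0)) {
      warning(sprintf("derivation %s is empty; skipped", name))
      next
    }
    a <- analytic_bandpass(x, fs, params$sigma_band[1], params$sigma_band[2])
    sig <- Re(a)
    env <- moving_average(Mod(a), max(1L, round(params$envelope_smooth_s * fs)))
    rel <- switch(params$threshold_mode,
                  mean_plus_k_sd = mean(env) + params$threshold_value * stats::sd(env),
                  percentile = stats::quantile(env, params$threshold_value / 100,
                                               names = FALSE))
    thr <- max(rel, params$min_abs_amplitude_uv)
    thresholds[d] <- thr
    above <- env > thr
    runs <- logical_runs(above)
    if (!nrow(runs)) { density[d] <- 0; next }
    ## drop runs crossing a segment boundary is handled by splitting:
    runs <- split_runs_at_boundaries(runs, seg)
    runs <- merge_runs(runs, gap = round(params$merge_gap_s * fs), seg = seg)
    durs <- (runs[, 2] - runs[, 1] + 1L) / fs
    keep <- durs >= params$min_dur_s & durs <= params$max_dur_s
    runs <- runs[keep, , drop = FALSE]
    if (!nrow(runs)) { density[d] <- 0; next }
    n_ev <- nrow(runs)
    stats_ev <- vapply(seq_len(n_ev), function(i) {
      xs <- sig[runs[i, 1]:runs[i, 2]]
      c(event_osc_frequency(xs, fs, params$sigma_band),
        event_mean_power(xs),
        max(env[runs[i, 1]:runs[i, 2]]))
    }, numeric(3))
    tab <- data.frame(subject_id = bip$subject_id, derivation = name,
                      onset_s = bip$time_s[runs[, 1]],
                      offset_s = bip$time_s[runs[, 2]] + 1 / fs,
                      duration_s = (runs[, 2] - runs[, 1] + 1L) / fs,
                      osc_freq_hz = stats_ev[1, ],
                      mean_power_uv2 = stats_ev[2, ],
                      peak_uv = stats_ev[3, ],
                      stringsAsFactors = FALSE)
    tab$band <- classify_band(tab$osc_freq_hz)
    density[d] <- nrow(tab) / (n / fs) * 60
    out[[d]] <- tab
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(subject_id = character(0), derivation = character(0),
                      onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), osc_freq_hz = numeric(0),
                      mean_power_uv2 = numeric(0), peak_uv = numeric(0),
                      band = character(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  class(res) <- c("spindle_events", class(res))
  attr(res, "thresholds") <- thresholds
  attr(res, "density_per_min") <- density
  attr(res, "params") <- params
  res
}

## Split supra-threshold runs at N2 segment boundaries.
split_runs_at_boundaries <- function(runs, seg) {
  if (length(unique(seg)) == 1L) return(runs)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    i0 <- runs[i, 1]; i1 <- runs[i, 2]
    s <- seg[i0:i1]
    if (s[1] == s[length(s)]) { out[[length(out) + 1L]] <- c(i0, i1); next }
    br <- which(diff(s) != 0)
    starts <- c(i0, i0 + br)
    ends <- c(i0 + br - 1L, i1)
    for (j in seq_along(starts)) out[[length(out) + 1L]] <- c(starts[j], ends[j])
  }
  do.call(rbind, out)
}

## Merge runs separated by less than `gap` samples (within one segment).
merge_runs <- function(runs, gap, seg) {
  if (nrow(runs) < 2L) return(runs)
  out <- list(runs[1, ])
  for (i in 2:nrow(runs)) {
    prev <- out[[length(out)]]
    same_seg <- seg[runs[i, 1]] == seg[prev[2]]
    if (same_seg && runs[i, 1] - prev[2] - 1L < gap) {
      out[[length(out)]] <- c(prev[1], runs[i, 2])
    } else {
      out[[length(out) + 1L]] <- runs[i, ]
    }
  }
  do.call(rbind, out)
}

#' Write events to a tab-separated file with run metadata
#'
#' @param events a `spindle_events` data frame.
#' @param path output TSV path; run metadata (detector parameters,
#'   thresholds, densities) is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events)[, c("subject_id", "derivation",
                                               "onset_s", "duration_s",
                                               "osc_freq_hz", "mean_power_uv2",
                                               "band")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(params = unclass(attr(events, "params")),
               thresholds = as.list(attr(events, "thresholds")),
               density_per_min = as.list(attr(events, "density_per_min")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
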