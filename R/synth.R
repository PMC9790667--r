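## Synthetic infant N2-sleep EEG with known ground truth.
##
## Subjects are built as ten referential channels: independent 1/f^a
## Gaussian background plus transient sigma-band spindle bursts injected as
## potential patterns over the electrodes of one hemisphere, mirrored
## simultaneously on the homologous electrodes with the lesioned side scaled
## by a per-region asymmetry factor. Because the five regional derivations
## are linear combinations of only four electrodes per hemisphere, any
## injected burst necessarily appears on more than one derivation (the
## montage satisfies FT = FC + CT and CO = CT + TO sample-wise). Patterns
## are therefore chosen so that all leakage is routed away from one
## "protected" region, whose measured asymmetry then reflects its injected
## factor alone; remaining leaks are either full-amplitude (detected on both
## hemispheres alike) or half-amplitude (below the detector's threshold at
## default settings).

HEMI_ELECTRODES <- list(left = c(Fp = "Fp1", C = "C3", T = "T3", O = "O1"),
                        right = c(Fp = "Fp2", C = "C4", T = "T4", O = "O2"))

## Region -> (node1, node2) in the abstract per-hemisphere montage graph.
REGION_NODES <- list(FC = c("Fp", "C"), FT = c("Fp", "T"), CT = c("C", "T"),
                     CO = c("C", "O"), TO = c("T", "O"))

#' Injection patterns for one protected region
#'
#' For every region, the referential potential pattern (coefficients over
#' electrodes Fp, C, T, O of one hemisphere) used to inject that region's
#' spindle events. Each pattern produces unit amplitude on its own
#' derivation and zero on the protected region's derivation; the protected
#' region's own pattern spreads its unavoidable leakage at half amplitude.
#'
#' @param protected region whose derivation stays free of leakage.
#' @return named list of numeric coefficient vectors over `c(Fp, C, T, O)`;
#'   attribute `leaks` gives each pattern's resulting derivation amplitudes.
#' @export
injection_patterns <- function(protected = "CO") {
  regions <- names(REGION_NODES)
  assert_that(protected %in% regions, "parameter",
              sprintf("unknown region '%s'", protected))
  nodes <- c("Fp", "C", "T", "O")
  amp_of <- function(v) {
    vapply(REGION_NODES, function(p) v[p[1]] - v[p[2]], numeric(1))
  }
  pn <- REGION_NODES[[protected]]
  ## node classes after contracting the protected edge
  class_of <- function(e) if (e %in% pn) pn else e
  out <- list()
  for (r in regions) {
    v <- stats::setNames(numeric(4), nodes)
    if (r == protected) {
      v[REGION_NODES[[r]][1]] <- 0.5
      v[REGION_NODES[[r]][2]] <- -0.5
    } else {
      ends <- REGION_NODES[[r]]
      cand <- lapply(seq_len(2), function(i) {
        w <- stats::setNames(numeric(4), nodes)
        w[class_of(ends[i])] <- if (i == 1) 1 else -1
        w
      })
      n_leaks <- vapply(cand, function(w) {
        a <- amp_of(w)
        sum(abs(a[setdiff(regions, r)]) > 1e-12)
      }, numeric(1))
      v <- cand[[which.min(n_leaks)]]
    }
    out[[r]] <- v
  }
  leaks <- do.call(rbind, lapply(out, amp_of))
  structure(out, leaks = leaks, protected = protected)
}

## Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic 1/f background
#'
#' Gaussian noise with power spectral density proportional to
#' `1/f^exponent` (flat below 0.5 Hz), scaled to the requested RMS.
#'
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz.
#' @param exponent spectral slope.
#' @param rms_uv target root-mean-square amplitude in microvolts.
#' @param seed integer seed (deterministic output).
#' @return numeric signal of `duration_s * fs` samples.
#' @export
synth_background <- function(duration_s, fs, exponent = 1.5, rms_uv = 10,
                             seed = 1) {
  synth_background_pair(duration_s, fs, exponent, rms_uv, seed)[[1]]
}

## Two independent 1/f channels from a single complex inverse FFT: with
## independent complex-Gaussian spectral coefficients, the real and
## imaginary parts of the inverse transform are independent real Gaussian
## processes sharing the prescribed spectrum.
synth_background_pair <- function(duration_s, fs, exponent = 1.5,
                                  rms_uv = 10, seed = 1) {
  assert_that(duration_s > 0, "parameter", "duration_s must be positive")
  n <- round(duration_s * fs)
  with_seed(seed, {
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
    shape <- pmax(abs(f), 0.5)^(-exponent / 2)
    shape[1] <- 0
    spec <- shape * complex(real = stats::rnorm(n),
                            imaginary = stats::rnorm(n))
    z <- stats::fft(spec, inverse = TRUE) / n
    lapply(list(Re(z), Im(z)), function(x) {
      x <- x - mean(x)
      x * rms_uv / sqrt(mean(x^2))
    })
  })
}

#' Synthetic spindle burst
#'
#' Tukey-tapered sinusoid. The analytic mean power of the pure waveform is
#' `amp^2 / 2 * w` where `w = mean(taper^2)` (about 0.69 for the default
#' taper).
#'
#' @param freq_hz oscillation frequency in Hz (11-15).
#' @param duration_s burst duration in seconds (0.5-3).
#' @param amp_uv peak amplitude in microvolts.
#' @param fs sampling rate in Hz.
#' @param phase initial phase in radians.
#' @param taper_alpha Tukey taper fraction.
#' @return numeric waveform of `round(duration_s * fs)` samples with
#'   attributes `freq_hz`, `duration_s`, `amp_uv`, `mean_power_uv2`
#'   (analytic).
#' @export
synth_spindle <- function(freq_hz, duration_s, amp_uv, fs = 256, phase = 0,
                          taper_alpha = 0.5) {
  assert_that(freq_hz >= 11 && freq_hz <= 15, "parameter",
              "spindle frequency must lie in 11-15 Hz")
  assert_that(duration_s >= 0.5 && duration_s <= 3, "parameter",
              "spindle duration must lie in 0.5-3 s")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  w <- tukey_window(n, taper_alpha)
  x <- amp_uv * w * sin(2 * pi * freq_hz * t + phase)
  structure(x, freq_hz = freq_hz, duration_s = duration_s, amp_uv = amp_uv,
            mean_power_uv2 = amp_uv^2 / 2 * mean(w^2))
}

#' Specification of one synthetic subject
#'
#' Defaults describe a realistic ten-minute infant N2 recording: spindle
#' bursts at two per minute and region at 256 Hz, frequencies drawn from an
#' equal mixture of a slow (about 12 Hz) and a fast (about 14 Hz) component,
#' durations uniform on 1-2 s, 30 microvolt peak amplitude over a 1/f^1.5
#' background of 10 microvolts RMS per electrode.
#'
#' @param subject_id identifier.
#' @param group `"UCP"` or `"typical"` (outcome label only).
#' @param lesion_side `"left"` or `"right"`.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param spindle_rate_per_min event rate per region.
#' @param freq_means,freq_sd,freq_weights mixture defining spindle
#'   frequencies (truncated 0.2 Hz away from the 13 Hz band boundary).
#' @param dur_range_s event duration range in seconds.
#' @param base_amp_uv peak amplitude of an unattenuated burst on its own
#'   derivation.
#' @param asymmetry named vector of per-region amplitude factors applied to
#'   lesioned-hemisphere spindles.
#' @param noise_exponent,noise_rms_uv background parameters.
#' @param bg_asymmetry amplitude factor applied to lesioned-hemisphere
#'   background (confounder knob; 1 = symmetric).
#' @param protected_region region kept free of injection leakage.
#' @param seed integer seed.
#' @return object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id = "S01", group = "typical",
                         lesion_side = "left", duration_s = 600, fs = 256,
                         spindle_rate_per_min = 2,
                         freq_means = c(12, 14), freq_sd = 0.4,
                         freq_weights = c(0.5, 0.5),
                         dur_range_s = c(1.0, 2.0),
                         base_amp_uv = 30,
                         asymmetry = c(FC = 1, FT = 1, CT = 1, CO = 1, TO = 1),
                         noise_exponent = 1.5, noise_rms_uv = 10,
                         bg_asymmetry = 1,
                         protected_region = "CO", seed = 1) {
  assert_that(all(asymmetry > 0), "parameter", "asymmetry factors must be > 0")
  assert_that(spindle_rate_per_min > 0, "parameter", "rate must be positive")
  assert_that(dur_range_s[1] >= 0.5 && dur_range_s[2] <= 3, "parameter",
              "durations must lie in [0.5, 3] s")
  asym <- stats::setNames(rep(1, 5), names(REGION_NODES))
  asym[names(asymmetry)] <- asymmetry
  structure(list(subject_id = subject_id, group = group,
                 lesion_side = lesion_side, duration_s = duration_s, fs = fs,
                 spindle_rate_per_min = spindle_rate_per_min,
                 freq_means = freq_means, freq_sd = freq_sd,
                 freq_weights = freq_weights, dur_range_s = dur_range_s,
                 base_amp_uv = base_amp_uv, asymmetry = asym,
                 noise_exponent = noise_exponent, noise_rms_uv = noise_rms_uv,
                 bg_asymmetry = bg_asymmetry,
                 protected_region = protected_region, seed = seed),
            class = "subject_spec")
}

## Draw one spindle frequency from the truncated two-component mixture.
draw_frequency <- function(spec) {
  repeat {
    k <- sample.int(length(spec$freq_means), 1, prob = spec$freq_weights)
    f <- stats::rnorm(1, spec$freq_means[k], spec$freq_sd)
    lo <- if (spec$freq_means[k] < 13) 11.2 else 13.2
    hi <- if (spec$freq_means[k] < 13) 12.8 else 14.8
    if (f >= lo && f <= hi) return(f)
  }
}

## Hardcore renewal schedule of event onsets within [lo, hi]: consecutive
## onsets at least `gap` apart, long-run rate `rate_per_s`.
schedule_onsets <- function(lo, hi, rate_per_s, gap) {
  mean_gap <- 1 / rate_per_s
  assert_that(mean_gap > gap + 0.2, "generation",
              "infeasible spindle rate: events cannot fit without overlap")
  onsets <- numeric(0)
  t <- lo + stats::rexp(1, 1 / (mean_gap - gap))
  while (t <= hi) {
    onsets <- c(onsets, t)
    t <- t + gap + stats::rexp(1, 1 / (mean_gap - gap))
  }
  onsets
}

#' Generate one synthetic subject
#'
#' Returns the referential recording, the full injection ground truth, and
#' the N2 annotations the pipeline consumes.
#'
#' @param spec a [subject_spec()].
#' @return list with elements `recording` (a [raw_recording()] with N2
#'   annotations), `truth` (data frame: one row per event and derivation
#'   carrying signal, with columns `region`, `derivation`, `side`,
#'   `onset_s`, `duration_s`, `freq_hz`, `amp_uv`, `component`
#'   = "primary"/"leak_full"/"leak_half"), `events` (one row per scheduled
#'   event), `segments` (N2 segments) and `spec`.
#' @export
synth_subject <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  regions <- names(REGION_NODES)
  patterns <- injection_patterns(spec$protected_region)
  leaks <- attr(patterns, "leaks")

  ## N2 sleep as two segments separated by a mid-recording arousal
  mid <- spec$duration_s / 2
  segments <- n2_segments(c(5, mid + 5), c(mid - 5, spec$duration_s - 5))

  out <- with_seed(spec$seed, {
    channels <- unlist(HEMI_ELECTRODES, use.names = FALSE)
    channels <- c(channels, "F3", "F4")
    data <- matrix(0, n, length(channels),
                   dimnames = list(NULL, channels))
    for (j in seq(1, length(channels), by = 2)) {
      pair <- synth_background_pair(spec$duration_s, fs, spec$noise_exponent,
                                    spec$noise_rms_uv,
                                    seed = derive_seed(spec$seed, j))
      data[, j] <- pair[[1]]
      data[, j + 1] <- pair[[2]]
    }
    if (spec$bg_asymmetry != 1) {
      les_ch <- HEMI_ELECTRODES[[spec$lesion_side]]
      data[, les_ch] <- data[, les_ch] * spec$bg_asymmetry
    }

    rate <- spec$spindle_rate_per_min * length(regions) / 60
    gap <- spec$dur_range_s[2] + 0.5
    onsets <- unlist(lapply(seq_len(nrow(segments)), function(s) {
      schedule_onsets(segments$start_s[s] + 3,
                      segments$end_s[s] - 3 - spec$dur_range_s[2],
                      rate, gap)
    }))
    n_ev <- length(onsets)
    ev_region <- sample(regions, n_ev, replace = TRUE)
    ev_freq <- vapply(seq_len(n_ev), function(i) draw_frequency(spec),
                      numeric(1))
    ev_dur <- stats::runif(n_ev, spec$dur_range_s[1], spec$dur_range_s[2])
    ev_phase <- stats::runif(n_ev, 0, 2 * pi)

    for (i in seq_len(n_ev)) {
      wav <- synth_spindle(ev_freq[i], ev_dur[i], spec$base_amp_uv, fs,
                           ev_phase[i])
      i0 <- round(onsets[i] * fs) + 1L
      idx <- i0:(i0 + length(wav) - 1L)
      coefs <- patterns[[ev_region[i]]]
      nz <- names(coefs)[abs(coefs) > 1e-12]
      for (side in c("left", "right")) {
        factor <- if (identical(side, spec$lesion_side))
          spec$asymmetry[ev_region[i]] else 1
        ch <- HEMI_ELECTRODES[[side]][nz]
        data[idx, ch] <- data[idx, ch] + outer(wav, coefs[nz] * factor)
      }
    }

    ## ground-truth table: one row per event x hemisphere x derivation
    ## carrying signal (primary target plus leakage components)
    deriv_name <- vapply(regions, function(r) {
      nodes <- REGION_NODES[[r]]
      paste(paste(HEMI_ELECTRODES$left[nodes[1]],
                  HEMI_ELECTRODES$left[nodes[2]], sep = "-"),
            paste(HEMI_ELECTRODES$right[nodes[1]],
                  HEMI_ELECTRODES$right[nodes[2]], sep = "-"),
            sep = "|")
    }, character(1))
    truth <- NULL
    if (n_ev > 0) {
      rows <- lapply(regions, function(r2) {
        coef <- abs(leaks[, r2])          # per source region
        src <- coef[ev_region] > 1e-12
        if (!any(src)) return(NULL)
        dv <- strsplit(deriv_name[r2], "|", fixed = TRUE)[[1]]
        do.call(rbind, lapply(c("left", "right"), function(side) {
          factor <- ifelse(rep(side == spec$lesion_side, sum(src)),
                           spec$asymmetry[ev_region[src]], 1)
          data.frame(region = ev_region[src],
                     derivation = dv[if (side == "left") 1 else 2],
                     side = side, onset_s = onsets[src],
                     duration_s = ev_dur[src], freq_hz = ev_freq[src],
                     amp_uv = coef[ev_region[src]] * factor * spec$base_amp_uv,
                     component = ifelse(ev_region[src] == r2, "primary",
                                        ifelse(coef[ev_region[src]] > 0.75,
                                               "leak_full", "leak_half")),
                     stringsAsFactors = FALSE)
        }))
      })
      truth <- do.call(rbind, rows)
      truth <- truth[order(truth$onset_s, truth$derivation), ]
      rownames(truth) <- NULL
    }
    ev_tab <- if (n_ev > 0) {
      data.frame(region = ev_region, onset_s = onsets, duration_s = ev_dur,
                 freq_hz = ev_freq,
                 band = ifelse(ev_freq < 13, "slow", "fast"),
                 stringsAsFactors = FALSE)
    } else NULL
    list(data = data, truth = truth, events = ev_tab)
  })
  data <- out$data

  ann <- data.frame(label = "N2",
                    start_s = segments$start_s, end_s = segments$end_s,
                    stringsAsFactors = FALSE)
  rec <- raw_recording(data, fs, spec$subject_id, annotations = ann)
  list(recording = rec, truth = out$truth, events = out$events,
       segments = segments, spec = spec)
}

#' Specification of a synthetic cohort
#'
#' Group sizes default to the study design this generator emulates: 13
#' infants with later unilateral cerebral palsy (UCP) and 27 with typical
#' outcome, about 55% left-sided lesions. Per-region asymmetry factors are
#' drawn log-normally; UCP location parameters are calibrated so that the
#' measured centro-occipital SPA medians land near 0.56 (UCP) versus 1.00
#' (typical), and dispersions reproduce the reported individual-level
#' separability of the biomarker.
#'
#' @param n_ucp,n_typical group sizes.
#' @param left_fraction probability of a left-sided lesion.
#' @param ucp_factor_median named per-region medians of the UCP amplitude
#'   factor `a` (measured SPA approximates `a^2` for the protected region).
#' @param ucp_factor_sdlog,typical_factor_sdlog log-scale spreads.
#' @param seed master seed.
#' @param ... forwarded to [subject_spec()] (e.g. `duration_s`).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ucp = 13, n_typical = 27, left_fraction = 0.55,
                        ucp_factor_median = c(FC = 0.889, FT = 0.812,
                                              CT = 0.872, CO = 0.748,
                                              TO = 0.959),
                        ucp_factor_sdlog = 0.02,
                        typical_factor_sdlog = 0.12,
                        seed = 1, ...) {
  assert_that(n_ucp >= 1 && n_typical >= 1, "parameter",
              "group sizes must be at least 1")
  structure(list(n_ucp = n_ucp, n_typical = n_typical,
                 left_fraction = left_fraction,
                 ucp_factor_median = ucp_factor_median,
                 ucp_factor_sdlog = ucp_factor_sdlog,
                 typical_factor_sdlog = typical_factor_sdlog,
                 seed = seed, subject_args = list(...)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject metadata and asymmetry factors; the EEG itself is
#' realized lazily per subject (via [synth_subject()]) to keep memory flat,
#' or written to EDF + sidecar files when `dir` is given.
#'
#' @param spec a [cohort_spec()].
#' @param dir if non-`NULL`, write per-subject EDF files plus `manifest.csv`
#'   (subject_id, edf_path, lesion_side, outcome, sex), an N2 sidecar CSV
#'   and a ground-truth events TSV into this directory.
#' @return object of class `synthetic_cohort`: `metadata` (data frame),
#'   `subject_specs` (list of [subject_spec()]), `spec`; with `dir`, also
#'   `paths`.
#' @export
synth_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_ucp + spec$n_typical
  regions <- names(REGION_NODES)
  meta <- with_seed(spec$seed, {
    group <- sample(rep(c("UCP", "typical"), c(spec$n_ucp, spec$n_typical)))
    side <- ifelse(stats::runif(n) < spec$left_fraction, "left", "right")
    sex <- sample(c("F", "M"), n, replace = TRUE)
    factors <- t(vapply(seq_len(n), function(i) {
      if (group[i] == "UCP") {
        stats::rlnorm(5, meanlog = log(spec$ucp_factor_median[regions]),
                      sdlog = spec$ucp_factor_sdlog)
      } else {
        stats::rlnorm(5, meanlog = 0, sdlog = spec$typical_factor_sdlog)
      }
    }, numeric(5)))
    colnames(factors) <- regions
    data.frame(subject_id = sprintf("S%02d", seq_len(n)),
               group = group, lesion_side = side, sex = sex, factors,
               stringsAsFactors = FALSE)
  })
  subject_specs <- lapply(seq_len(n), function(i) {
    do.call(subject_spec, c(list(
      subject_id = meta$subject_id[i], group = meta$group[i],
      lesion_side = meta$lesion_side[i],
      asymmetry = stats::setNames(as.numeric(meta[i, regions]), regions),
      seed = derive_seed(spec$seed, 1000 + i)),
      spec$subject_args))
  })
  out <- structure(list(metadata = meta, subject_specs = subject_specs,
                        spec = spec),
                   class = "synthetic_cohort")
  if (!is.null(dir)) out <- write_cohort(out, dir)
  out
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$metadata
  paths <- character(nrow(meta))
  truth_all <- list()
  n2_all <- list()
  for (i in seq_len(nrow(meta))) {
    sub <- synth_subject(cohort$subject_specs[[i]])
    paths[i] <- file.path(dir, paste0(meta$subject_id[i], ".edf"))
    write_edf(sub$recording, paths[i])
    truth_all[[i]] <- cbind(subject_id = meta$subject_id[i], sub$truth)
    n2_all[[i]] <- data.frame(subject_id = meta$subject_id[i],
                              start_s = sub$segments$start_s,
                              end_s = sub$segments$end_s)
  }
  manifest <- data.frame(subject_id = meta$subject_id, edf_path = paths,
                         lesion_side = meta$lesion_side,
                         outcome = meta$group, sex = meta$sex,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, n2_all), file.path(dir, "n2_segments.csv"),
                   row.names = FALSE)
  utils::write.table(do.call(rbind, truth_all),
                     file.path(dir, "ground_truth_events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cohort$paths <- paths
  cohort$dir <- dir
  cohort
}

#' Ground-truth SPA of a synthetic subject
#'
#' The asymptotic SPA implied by the injected amplitude factors: `a^2` for
#' the protected region; for other regions, the detected-event blend of the
#' region's own factor with the factors of the regions whose full-amplitude
#' leakage lands on it.
#'
#' @param spec a [subject_spec()].
#' @return named vector of 5 per-region ground-truth SPA values.
#' @export
ground_truth_spa <- function(spec) {
  patterns <- injection_patterns(spec$protected_region)
  leaks <- attr(patterns, "leaks")
  a <- spec$asymmetry
  vapply(names(REGION_NODES), function(r) {
    contrib <- abs(leaks[, r]) >= 0.75   # full-amplitude components only
    w <- leaks[contrib, r]^2
    src <- rownames(leaks)[contrib]
    sum(w * a[src]^2) / sum(w)
  }, numeric(1))
}
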