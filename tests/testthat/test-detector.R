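test_that("sigma envelope tracks sinusoid amplitude", {
  fs <- 256
  t <- seq_len(fs * 20) / fs
  x <- sigma_filter(3 * sin(2 * pi * 12 * t), fs)
  env <- sigma_envelope(x, fs)
  mid <- seq(fs * 4, fs * 16)
  expect_lt(max(abs(env[mid] - 3)) / 3, 0.1)
  expect_equal(sigma_envelope(numeric(fs * 4), fs), numeric(fs * 4))

  ## amplitude step A -> 2A doubles the envelope plateau
  x2 <- c(sin(2 * pi * 12 * t[1:(fs * 10)]),
          2 * sin(2 * pi * 12 * t[1:(fs * 10)]))
  env2 <- sigma_envelope(sigma_filter(x2, fs), fs)
  p1 <- mean(env2[seq(fs * 2, fs * 8)])
  p2 <- mean(env2[seq(fs * 12, fs * 18)])
  expect_equal(p2 / p1, 2, tolerance = 0.1)
  expect_error(sigma_envelope(x, fs, smooth_s = 0.05),
               class = "spindlespa_parameter_error")
})

test_that("a single embedded burst yields exactly one event at the right time", {
  bursts <- data.frame(electrode = "C3", t0 = 151.3, dur = 1.0,
                       freq = 12, amp = 30)
  bip <- burst_bipolar(duration_s = 320, noise_rms = 5, bursts = bursts,
                       seed = 21)
  ev <- detect_spindles(bip)
  on_co <- ev[ev$derivation == "C3-O1", ]
  expect_equal(nrow(on_co), 1)
  expect_lt(abs(on_co$onset_s - 151.3), 0.25)
  expect_equal(on_co$osc_freq_hz, 12, tolerance = 0.5)
  expect_equal(on_co$band, "slow")
})

test_that("duration and merge criteria are enforced", {
  ## 0.2 s burst is below min_dur_s and must be rejected
  fs <- 256
  n <- 320 * fs
  chans <- standard_electrodes()
  d <- matrix(rnorm(n * 10, sd = 1), n, 10, dimnames = list(NULL, chans))
  w <- 30 * sin(2 * pi * 12 * seq_len(round(0.2 * fs)) / fs)
  i0 <- 100 * fs
  d[i0:(i0 + length(w) - 1), "C3"] <- d[i0:(i0 + length(w) - 1), "C3"] + w
  rec <- raw_recording(d, fs, "D1",
                       annotations = data.frame(label = "N2", start_s = 0,
                                                end_s = 320))
  ev <- detect_spindles(extract_n2(rec))
  expect_equal(nrow(ev[ev$derivation == "C3-O1", ]), 0)

  ## two bursts separated by 0.1 s (< merge gap) merge into one event
  w1 <- 30 * sin(2 * pi * 12 * seq_len(round(0.6 * fs)) / fs)
  gap <- round(0.1 * fs)
  d2 <- matrix(rnorm(n * 10, sd = 1), n, 10, dimnames = list(NULL, chans))
  j0 <- 100 * fs
  d2[j0:(j0 + length(w1) - 1), "C3"] <- d2[j0:(j0 + length(w1) - 1), "C3"] + w1
  j1 <- j0 + length(w1) + gap
  d2[j1:(j1 + length(w1) - 1), "C3"] <- d2[j1:(j1 + length(w1) - 1), "C3"] + w1
  rec2 <- raw_recording(d2, fs, "D2",
                        annotations = data.frame(label = "N2", start_s = 0,
                                                 end_s = 320))
  ev2 <- detect_spindles(extract_n2(rec2))
  on_co <- ev2[ev2$derivation == "C3-O1", ]
  expect_equal(nrow(on_co), 1)
  expect_gt(on_co$duration_s, 1.2)
})

test_that("event frequency estimation is accurate and ties break low", {
  fs <- 256
  mk <- function(f, dur = 1) {
    w <- synth_spindle(f, dur, 20, fs)
    as.numeric(w) + rnorm(length(w), sd = 0.1)
  }
  expect_equal(event_osc_frequency(mk(12), fs), 12, tolerance = 0.5)
  f145 <- event_osc_frequency(mk(14.5), fs)
  expect_equal(f145, 14.5, tolerance = 0.5)
  expect_equal(classify_band(f145), "fast")
  ## exactly equal 11.5 + 14.5 components: documented tie-break to the lower
  t <- seq_len(fs) / fs
  x <- sin(2 * pi * 11.5 * t) + sin(2 * pi * 14.5 * t)
  expect_lt(event_osc_frequency(x, fs), 13)
  expect_error(event_osc_frequency(rnorm(20), fs),
               class = "spindlespa_estimation_error")
})

test_that("event mean power matches the analytic sinusoid value", {
  fs <- 256
  t <- seq_len(fs * 2) / fs
  x10 <- 10 * sin(2 * pi * 13 * t)
  expect_equal(event_mean_power(x10), 50, tolerance = 5)
  expect_equal(event_mean_power(2 * x10) / event_mean_power(x10), 4,
               tolerance = 1e-9)
  ## two bursts with amplitudes 10 and 20 -> power ratio ~0.25
  w1 <- synth_spindle(12, 1, 10, fs)
  w2 <- synth_spindle(12, 1, 20, fs)
  expect_equal(event_mean_power(as.numeric(w1)) /
                 event_mean_power(as.numeric(w2)), 0.25, tolerance = 0.01)
})

test_that("band classification respects the 13 Hz boundary rule", {
  expect_equal(classify_band(c(12.2, 13.0, 14.9)), c("slow", "fast", "fast"))
  expect_error(classify_band(16), class = "spindlespa_parameter_error")
})

test_that("detected events respect duration bounds and never overlap", {
  sub <- synth_subject(quick_spec(seed = 23))
  ev <- detect_spindles(extract_n2(sub$recording, sub$segments))
  p <- detector_params()
  expect_true(all(ev$duration_s >= p$min_dur_s - 1e-9))
  expect_true(all(ev$duration_s <= p$max_dur_s + 1e-9))
  for (d in unique(ev$derivation)) {
    e <- ev[ev$derivation == d, ]
    e <- e[order(e$onset_s), ]
    if (nrow(e) > 1) expect_true(all(diff(e$onset_s) >= e$duration_s[-nrow(e)]))
  }
  ## slow + fast counts partition the full count on every derivation
  expect_equal(sum(ev$band == "slow") + sum(ev$band == "fast"), nrow(ev))
  ## excluded derivations are skipped
  bip <- extract_n2(sub$recording, sub$segments)
  bip$excluded <- "C3-O1"
  ev2 <- detect_spindles(bip)
  expect_false("C3-O1" %in% ev2$derivation)
})

test_that("amplitude scaling is power-equivariant", {
  bursts <- data.frame(electrode = rep("C3", 8),
                       t0 = seq(20, 280, length.out = 8), dur = 1.2,
                       freq = 12.5, amp = 30)
  bip <- burst_bipolar(duration_s = 320, noise_rms = 5, bursts = bursts,
                       seed = 24)
  k <- 2.5
  bip2 <- bip
  bip2$data <- bip2$data * k
  p <- detector_params()
  p2 <- detector_params(min_abs_amplitude_uv = p$min_abs_amplitude_uv * k)
  e1 <- detect_spindles(bip, p)
  e2 <- detect_spindles(bip2, p2)
  co1 <- e1[e1$derivation == "C3-O1", ]
  co2 <- e2[e2$derivation == "C3-O1", ]
  expect_equal(nrow(co1), nrow(co2))
  expect_equal(co2$mean_power_uv2, k^2 * co1$mean_power_uv2, tolerance = 1e-8)
})
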