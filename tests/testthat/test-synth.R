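test_that("background noise meets its RMS and determinism contracts", {
  x <- synth_background(30, 256, exponent = 1.5, rms_uv = 10, seed = 61)
  expect_equal(sqrt(mean(x^2)), 10, tolerance = 0.5)
  expect_identical(x, synth_background(30, 256, 1.5, 10, seed = 61))
  expect_false(identical(x, synth_background(30, 256, 1.5, 10, seed = 62)))
  ## exponent 0 -> flat spectrum: equal band powers
  y <- synth_background(120, 256, exponent = 0, rms_uv = 10, seed = 63)
  p <- Mod(fft(y))^2
  f <- (seq_along(y) - 1) * 256 / length(y)
  b1 <- mean(p[f >= 1 & f <= 10])
  b2 <- mean(p[f >= 11 & f <= 20])
  expect_equal(b1 / b2, 1, tolerance = 0.1)
})

test_that("spindle waveforms have the documented length, power and recovery", {
  w <- synth_spindle(12, 1.0, 30, fs = 256)
  expect_length(w, 256)
  expect_equal(attr(w, "mean_power_uv2"),
               30^2 / 2 * mean(tukey_window(256, 0.5)^2))
  expect_equal(mean(as.numeric(w)^2), attr(w, "mean_power_uv2"),
               tolerance = 0.02 * attr(w, "mean_power_uv2"))
  expect_true(all(synth_spindle(12, 1, 0, 256) == 0))
  expect_error(synth_spindle(9, 1, 30), class = "spindlespa_parameter_error")
})

test_that("injection patterns respect the montage identities", {
  for (prot in names(region_map())) {
    pat <- injection_patterns(prot)
    leaks <- attr(pat, "leaks")
    for (r in rownames(leaks)) {
      ## unit amplitude on the target region
      expect_equal(unname(leaks[r, r]), 1)
      ## nothing ever leaks onto the protected region
      if (r != prot) expect_equal(unname(leaks[r, prot]), 0)
      ## every pattern satisfies FT = FC + CT and CO = CT + TO
      expect_equal(unname(leaks[r, "FT"]),
                   unname(leaks[r, "FC"] + leaks[r, "CT"]))
      expect_equal(unname(leaks[r, "CO"]),
                   unname(leaks[r, "CT"] + leaks[r, "TO"]))
    }
    ## the protected region's own leakage is half-amplitude
    others <- setdiff(colnames(leaks), prot)
    expect_lte(max(abs(leaks[prot, others])), 0.5 + 1e-12)
  }
})

test_that("symmetric subjects give SPA near one, asymmetric near a^2", {
  sub <- synth_subject(subject_spec(subject_id = "S1", lesion_side = "left",
                                    seed = 64))
  res <- process_subject(sub$recording, "left", run_config(),
                         segments = sub$segments)
  expect_true(all(abs(res$indexes$spa - 1) < 0.15))

  spa <- subject_spec(subject_id = "S2", lesion_side = "right",
                      asymmetry = c(CO = 0.8), seed = 65)
  sub2 <- synth_subject(spa)
  res2 <- process_subject(sub2$recording, "right", run_config(),
                          segments = sub2$segments)
  expect_equal(unname(res2$indexes$spa["CO_full_SPA"]), 0.64, tolerance = 0.1)
  others <- setdiff(names(res2$indexes$spa),
                    c("CO_full_SPA", "CO_slow_SPA", "CO_fast_SPA"))
  expect_true(all(abs(res2$indexes$spa[others] - 1) < 0.15))
  expect_equal(unname(ground_truth_spa(spa)["CO"]), 0.64)
})

test_that("event scheduling matches the requested rate", {
  sp <- subject_spec(subject_id = "R1", spindle_rate_per_min = 3,
                     duration_s = 600, seed = 66)
  sub <- synth_subject(sp)
  ## ~3/min/region over ~9.3 scheduled minutes; hardcore spacing keeps the
  ## count inside a generous Poisson-like band
  per_region <- table(sub$events$region)
  expect_true(all(per_region > 12 & per_region < 45))
  expect_error(synth_subject(subject_spec(spindle_rate_per_min = 8)),
               class = "spindlespa_generation_error")
})

test_that("cohorts are reproducible and match the design counts", {
  cs <- cohort_spec(seed = 67)
  co <- synth_cohort(cs)
  expect_equal(nrow(co$metadata), 40)
  expect_equal(sum(co$metadata$group == "UCP"), 13)
  co2 <- synth_cohort(cohort_spec(seed = 67))
  expect_identical(co$metadata, co2$metadata)
  ## different seeds give different draws
  expect_false(identical(co$metadata,
                         synth_cohort(cohort_spec(seed = 68))$metadata))
  ## written cohort has the documented file layout
  dir <- withr::local_tempdir()
  small <- synth_cohort(cohort_spec(n_ucp = 1, n_typical = 1, seed = 69,
                                    duration_s = 340), dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "n2_segments.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth_events.tsv")))
  expect_length(small$paths, 2)
  expect_true(all(file.exists(small$paths)))
})

test_that("pipeline SPA tracks ground-truth SPA across varied asymmetry", {
  factors <- c(0.5, 0.7, 0.85, 1, 1.15, 1.3)
  est <- truth <- numeric(0)
  for (i in seq_along(factors)) {
    sp <- subject_spec(subject_id = sprintf("G%02d", i), lesion_side = "left",
                       asymmetry = c(CO = factors[i], FC = 1 / factors[i]),
                       seed = 70 + i)
    sub <- synth_subject(sp)
    res <- process_subject(sub$recording, "left", run_config(),
                           segments = sub$segments)
    gt <- ground_truth_spa(sp)
    est <- c(est, res$indexes$spa[paste0(names(gt), "_full_SPA")])
    truth <- c(truth, gt)
  }
  expect_gte(cor(est, truth), 0.9)
})

test_that("detected event counts track injected counts", {
  sub <- synth_subject(subject_spec(subject_id = "C1", seed = 77))
  ev <- detect_spindles(extract_n2(sub$recording, sub$segments))
  strong <- sub$truth[sub$truth$component != "leak_half", ]
  for (d in unique(strong$derivation)) {
    injected <- sum(strong$derivation == d)
    detected <- sum(ev$derivation == d)
    expect_lt(abs(detected - injected), 0.2 * injected + 2)
  }
})
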