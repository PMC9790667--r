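fake_events <- function(rows) {
  ev <- data.frame(subject_id = "F01",
                   derivation = vapply(rows, `[[`, "", 1),
                   band = vapply(rows, `[[`, "", 2),
                   mean_power_uv2 = vapply(rows, function(r) as.numeric(r[[3]]),
                                           numeric(1)),
                   stringsAsFactors = FALSE)
  ev$osc_freq_hz <- ifelse(ev$band == "slow", 12, 14)
  ev$onset_s <- seq_len(nrow(ev))
  ev
}

test_that("regional band power averages event powers", {
  ev <- fake_events(list(list("C3-O1", "fast", 40), list("C3-O1", "fast", 60),
                         list("C3-O1", "slow", 30)))
  expect_equal(regional_band_power(ev, "CO", "fast", "left"), 50)
  expect_equal(regional_band_power(ev, "CO", "slow", "left"), 30)
  ## full band pools all events
  expect_equal(regional_band_power(ev, "CO", "full", "left"), mean(c(40, 60, 30)))
  ## no events -> missing with a reason
  p <- regional_band_power(ev, "FT", "fast", "right")
  expect_true(is.na(p))
  expect_equal(attr(p, "reason"), "no events")
  ## excluded channel -> missing
  p2 <- regional_band_power(ev, "CO", "fast", "left", excluded = "C3-O1")
  expect_equal(attr(p2, "reason"), "excluded channel")
  expect_error(regional_band_power(ev, "XX", "fast", "left"),
               class = "spindlespa_parameter_error")
})

test_that("full-band power lies between the sub-band powers", {
  ev <- fake_events(list(list("C3-O1", "slow", 20), list("C3-O1", "slow", 30),
                         list("C3-O1", "fast", 55)))
  full <- regional_band_power(ev, "CO", "full", "left")
  slow <- regional_band_power(ev, "CO", "slow", "left")
  fast <- regional_band_power(ev, "CO", "fast", "left")
  expect_gte(full, min(slow, fast))
  expect_lte(full, max(slow, fast))
})

test_that("the SPA ratio behaves as documented", {
  expect_equal(compute_spa(50, 50), 1.0)
  expect_equal(compute_spa(32.5, 50), 0.65)
  expect_true(is.na(compute_spa(NA, 50)))
  expect_error(compute_spa(-1, 50), class = "spindlespa_domain_error")
})

test_that("lesion side fixes the numerator hemisphere", {
  ev <- fake_events(list(list("C3-O1", "fast", 25), list("C4-O2", "fast", 100)))
  left <- spa_indexes(ev, "left")
  right <- spa_indexes(ev, "right")
  expect_equal(unname(left$spa["CO_fast_SPA"]), 0.25)
  expect_equal(unname(right$spa["CO_fast_SPA"]), 4)
  ## side anti-symmetry: swapping the label inverts each present SPA
  both <- !is.na(left$spa) & !is.na(right$spa)
  expect_equal(right$spa[both], 1 / left$spa[both])
  expect_equal(length(left$spa), 15)
})

test_that("SPA is invariant to global amplitude rescaling", {
  sub <- synth_subject(quick_spec(seed = 31, asymmetry = c(CO = 0.8)))
  e1 <- detect_spindles(extract_n2(sub$recording, sub$segments))
  rec2 <- sub$recording
  rec2$data <- rec2$data * 4
  p2 <- detector_params(min_abs_amplitude_uv = 4 * 5)
  e2 <- detect_spindles(extract_n2(rec2, sub$segments), p2)
  s1 <- spa_indexes(e1, "left")$spa
  s2 <- spa_indexes(e2, "left")$spa
  expect_equal(s2, s1, tolerance = 1e-6)
})

test_that("cohort tables have one row per subject and reject duplicates", {
  ev <- fake_events(list(list("C3-O1", "fast", 50), list("C4-O2", "fast", 50)))
  s1 <- spa_indexes(ev, "left", subject_id = "A")
  s2 <- spa_indexes(ev, "left", subject_id = "B")
  tab <- spa_table(list(s1, s2), outcomes = c(A = "UCP", B = "typical"))
  expect_equal(nrow(tab), 2)
  expect_equal(ncol(tab), 3 + 15)
  expect_equal(tab$outcome, c("UCP", "typical"))
  ## identical hemispheres -> all present values 1
  expect_true(all(na.omit(unlist(tab[1, spa_index_names()])) == 1))
  expect_error(spa_table(list(s1, s1)), class = "spindlespa_validation_error")
})
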