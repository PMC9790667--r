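test_that("EDF round-trip preserves labels, rate and samples", {
  rec <- burst_recording(duration_s = 12, noise_rms = 15, seed = 3)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(colnames(back$data), colnames(rec$data))
  expect_equal(back$fs, rec$fs)
  ## within 16-bit quantization of the +-100 uV physical range
  expect_lt(max(abs(back$data - rec$data)), 2 * 200 / 65535)
})

test_that("EDF+ annotations survive the round-trip", {
  rec <- burst_recording(duration_s = 12, seed = 4)
  rec$annotations <- data.frame(label = c("N2", "N2", "BAD_C3-O1"),
                                start_s = c(1, 6.5, 3),
                                end_s = c(5, 11, 3.5),
                                stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  ## annotations come back in record order; compare as sets ordered by onset
  a <- back$annotations[order(back$annotations$start_s), ]
  b <- rec$annotations[order(rec$annotations$start_s), ]
  expect_equal(a$label, b$label)
  expect_equal(a$start_s, b$start_s, tolerance = 1e-6)
  expect_equal(a$end_s, b$end_s, tolerance = 1e-6)
})

test_that("missing required electrodes raise a channel error naming them", {
  rec <- burst_recording(duration_s = 6, seed = 5)
  rec$data <- rec$data[, setdiff(colnames(rec$data), "O2")]
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  err <- expect_error(read_edf(path), class = "spindlespa_channel_error")
  expect_match(conditionMessage(err), "O2")
  ## but reading without requirements succeeds
  expect_s3_class(read_edf(path, require = NULL), "raw_recording")
})

test_that("unreadable files raise an I/O error", {
  expect_error(read_edf(file.path(tempdir(), "nope.edf")),
               class = "spindlespa_io_error")
  path <- withr::local_tempfile(fileext = ".edf")
  writeLines("not an edf", path)
  expect_error(read_edf(path), class = "spindlespa_io_error")
})

test_that("vendor-style channel labels resolve to bare electrodes", {
  expect_equal(spindlespa:::normalize_label(c("EEG Fp1-REF", "C3-A1", " t3 ")),
               c("FP1", "C3", "T3"))
})

test_that("an independent EDF reader agrees with ours", {
  ## cross-check the hand-rolled writer against python-mne when available
  has_mne <- nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote("import mne")),
            stdout = FALSE, stderr = FALSE) == 0
  if (!has_mne) succeed("python mne not available; round-trip already tested")
  if (has_mne) {
    rec <- burst_recording(duration_s = 8, seed = 6)
    path <- withr::local_tempfile(fileext = ".edf")
    write_edf(rec, path)
    out <- system2("python", c("-c", shQuote(paste0(
      "import mne,sys;",
      "raw=mne.io.read_raw_edf('", path, "',verbose='ERROR');",
      "x=raw.get_data()*1e6;",
      "print(raw.info['sfreq'], x.shape[0], x.shape[1], x[4,100])"
    ))), stdout = TRUE, stderr = FALSE)
    vals <- as.numeric(strsplit(trimws(out[length(out)]), " ")[[1]])
    expect_equal(vals[1], 256)
    expect_equal(vals[2], 10)
    expect_equal(vals[3], nrow(rec$data))
    expect_equal(vals[4], unname(rec$data[101, 5]), tolerance = 0.01)
  }
})
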