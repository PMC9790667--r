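#' Standard 10-electrode set
#'
#' The referential electrodes (international 10-20 system) required for the
#' bipolar spindle montage.
#' @return character vector of electrode names.
#' @export
standard_electrodes <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "T3", "T4", "O1", "O2")
}

#' Standard bipolar spindle montage
#'
#' Ten derivations: the eight-derivation longitudinal clinical montage plus
#' the centro-temporal pair (C3-T3, C4-T4), synthesized from referential
#' channels so that five homologous left/right region pairs are available.
#' @return character vector of derivation names, left hemisphere first.
#' @export
standard_derivations <- function() {
  c("Fp1-C3", "C3-O1", "Fp1-T3", "T3-O1", "C3-T3",
    "Fp2-C4", "C4-O2", "Fp2-T4", "T4-O2", "C4-T4")
}

#' Region-to-derivation map
#'
#' Five scalp regions, each a homologous (left, right) derivation pair:
#' fronto-central (FC), fronto-temporal (FT), centro-temporal (CT),
#' centro-occipital (CO) and temporo-occipital (TO). The map is a named list
#' so alternative montages can be supplied wherever a region map is accepted.
#'
#' @return named list of `c(left, right)` derivation pairs.
#' @export
region_map <- function() {
  list(FC = c("Fp1-C3", "Fp2-C4"),
       FT = c("Fp1-T3", "Fp2-T4"),
       CT = c("C3-T3", "C4-T4"),
       CO = c("C3-O1", "C4-O2"),
       TO = c("T3-O1", "T4-O2"))
}

## Normalize an EDF channel label to a bare electrode name: strip "EEG "
## prefixes and reference suffixes ("-REF", "-A1", ...), case-insensitive.
normalize_label <- function(x) {
  x <- trimws(x)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("[-_ ](REF|A1|A2|M1|M2|AVG|LE)$", "", x, ignore.case = TRUE)
  toupper(x)
}

## Positions of `wanted` electrodes among `labels`; errors (naming the
## missing electrodes) when error = TRUE.
match_electrodes <- function(labels, wanted, error = FALSE) {
  if (is.null(wanted) || !length(wanted)) return(integer(0))
  pos <- match(normalize_label(wanted), normalize_label(labels))
  if (error && anyNA(pos)) {
    spa_error("channel",
              sprintf("required electrode(s) missing: %s",
                      paste(wanted[is.na(pos)], collapse = ", ")),
              missing = wanted[is.na(pos)])
  }
  pos
}

#' Referential EEG recording
#'
#' @param data numeric matrix, one column per channel (microvolts), with
#'   channel labels as column names.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param annotations data frame with columns `label`, `start_s`, `end_s`
#'   (seconds from recording start, half-open intervals).
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, subject_id = "anonymous",
                          annotations = NULL) {
  assert_that(is.matrix(data) && is.numeric(data) && !is.null(colnames(data)),
              "validation", "data must be a labelled numeric matrix")
  assert_that(is_number(fs) && fs > 0, "validation", "fs must be positive")
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(0), start_s = numeric(0),
                              end_s = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(data = data, fs = fs, subject_id = subject_id,
                 annotations = annotations),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s: %d channels x %.1f s @ %g Hz, %d annotations\n",
              x$subject_id, ncol(x$data), nrow(x$data) / x$fs, x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a recording object.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) nrow(rec$data) / rec$fs

#' Band-pass filter a recording
#'
#' Applies the acquisition band (default 0.3-70 Hz) to every channel with a
#' zero-phase filter; DC offsets are removed. Recordings not at the target
#' rate are first resampled with an anti-aliasing filter.
#'
#' @param rec a [raw_recording()].
#' @param hp_hz,lp_hz high-/low-pass cut-offs in Hz.
#' @param target_fs if non-`NULL`, resample to this rate first (default
#'   256 Hz, the native clinical rate).
#' @return filtered [raw_recording()].
#' @export
apply_filters <- function(rec, hp_hz = 0.3, lp_hz = 70, target_fs = 256) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is.null(target_fs) && rec$fs != target_fs) {
    rec$data <- apply(rec$data, 2, resample_signal,
                      fs_from = rec$fs, fs_to = target_fs)
    rec$fs <- target_fs
  }
  assert_that(lp_hz < rec$fs / 2, "parameter",
              "low-pass cut-off must be below Nyquist")
  assert_that(hp_hz < lp_hz, "parameter", "hp_hz must be below lp_hz")
  nc <- ncol(rec$data)
  for (j in seq(1, nc, by = 2)) {
    if (j + 1 <= nc) {
      pair <- fft_bandpass_pair(rec$data[, j], rec$data[, j + 1], rec$fs,
                                hp_hz, lp_hz)
      rec$data[, j] <- pair[[1]]
      rec$data[, j + 1] <- pair[[2]]
    } else {
      rec$data[, j] <- fft_bandpass(rec$data[, j], rec$fs, hp_hz, lp_hz)
    }
  }
  rec
}

#' Build the bipolar montage
#'
#' Each derivation is the sample-wise difference between its two referential
#' electrodes.
#'
#' @param rec a [raw_recording()] containing the ten standard electrodes.
#' @param derivations derivation names of the form `"A-B"`.
#' @param excluded character vector of derivations to mark as bad (they are
#'   kept in the object but skipped by the detector).
#' @return object of class `bipolar_recording` with fields `data`
#'   (matrix, one column per derivation), `fs`, `subject_id`, `excluded`.
#' @export
make_bipolar <- function(rec, derivations = standard_derivations(),
                         excluded = character(0)) {
  stopifnot(inherits(rec, "raw_recording"))
  labels <- colnames(rec$data)
  pairs <- strsplit(derivations, "-", fixed = TRUE)
  electrodes <- unique(unlist(pairs))
  pos <- match_electrodes(labels, electrodes, error = TRUE)
  names(pos) <- electrodes
  out <- vapply(pairs, function(p) {
    rec$data[, pos[p[1]]] - rec$data[, pos[p[2]]]
  }, numeric(nrow(rec$data)))
  colnames(out) <- derivations
  structure(list(data = out, fs = rec$fs, subject_id = rec$subject_id,
                 excluded = intersect(excluded, derivations),
                 annotations = rec$annotations,
                 time_s = (seq_len(nrow(out)) - 1L) / rec$fs),
            class = "bipolar_recording")
}

#' @export
print.bipolar_recording <- function(x, ...) {
  cat(sprintf("<bipolar_recording> %s: %d derivations x %.1f s @ %g Hz\n",
              x$subject_id, ncol(x$data), nrow(x$data) / x$fs, x$fs))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' N2 sleep segments
#'
#' Validates, sorts and merges overlapping segments.
#'
#' @param start_s,end_s numeric vectors of segment bounds in seconds
#'   (half-open intervals from recording start).
#' @return data frame with columns `start_s`, `end_s`.
#' @export
n2_segments <- function(start_s, end_s) {
  assert_that(length(start_s) == length(end_s), "validation",
              "start_s and end_s must have the same length")
  assert_that(all(end_s > start_s), "validation",
              "every segment must satisfy end_s > start_s")
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  if (length(start_s) > 1L) {
    keep_s <- start_s[1]; keep_e <- end_s[1]
    for (i in 2:length(start_s)) {
      k <- length(keep_s)
      if (start_s[i] <= keep_e[k]) {
        keep_e[k] <- max(keep_e[k], end_s[i])
      } else {
        keep_s <- c(keep_s, start_s[i]); keep_e <- c(keep_e, end_s[i])
      }
    }
    start_s <- keep_s; end_s <- keep_e
  }
  data.frame(start_s = start_s, end_s = end_s)
}

## N2 segments from a recording's annotations (labels "N2_START"/"N2_END"
## written as paired markers, or interval annotations labelled "N2").
n2_from_annotations <- function(ann) {
  iv <- ann[ann$label == "N2", , drop = FALSE]
  if (nrow(iv)) return(n2_segments(iv$start_s, iv$end_s))
  st <- sort(ann$start_s[ann$label == "N2_START"])
  en <- sort(ann$start_s[ann$label == "N2_END"])
  if (length(st) && length(st) == length(en)) return(n2_segments(st, en))
  data.frame(start_s = numeric(0), end_s = numeric(0))
}

#' Extract N2-sleep data on the bipolar montage
#'
#' Builds the bipolar montage and restricts it to the annotated N2 segments.
#' A per-sample map back to original recording time is retained so that event
#' onsets can be reported in recording time. Subjects with less than
#' `min_total_s` of N2 sleep are refused with an eligibility error.
#'
#' @param rec a [raw_recording()] (or an existing `bipolar_recording`).
#' @param segments data frame from [n2_segments()]; if `NULL`, segments are
#'   taken from the recording's annotations.
#' @param min_total_s minimum total N2 duration in seconds (default 300 s,
#'   i.e. five minutes).
#' @param ... passed to [make_bipolar()].
#' @return `bipolar_recording` restricted to N2 samples, with `time_s` giving
#'   each retained sample's original time and `segment` its segment index.
#' @export
extract_n2 <- function(rec, segments = NULL, min_total_s = 300, ...) {
  bip <- if (inherits(rec, "bipolar_recording")) rec else make_bipolar(rec, ...)
  if (is.null(segments)) segments <- n2_from_annotations(bip$annotations)
  segments <- n2_segments(segments$start_s, segments$end_s)
  dur <- nrow(bip$data) / bip$fs
  assert_that(nrow(segments) > 0, "eligibility", "no N2 segments available")
  assert_that(all(segments$start_s >= 0) && all(segments$end_s <= dur + 1e-9),
              "validation", "N2 segment extends past the end of the recording")
  total <- sum(segments$end_s - segments$start_s)
  if (total < min_total_s) {
    spa_error("eligibility",
              sprintf("subject %s has %.1f s of N2 sleep (minimum %.0f s)",
                      bip$subject_id, total, min_total_s))
  }
  idx <- integer(0)
  seg_id <- integer(0)
  for (i in seq_len(nrow(segments))) {
    ## half-open [start, end): sample k covers time (k-1)/fs
    lo <- floor(segments$start_s[i] * bip$fs) + 1L
    hi <- min(ceiling(segments$end_s[i] * bip$fs), nrow(bip$data))
    idx <- c(idx, lo:hi)
    seg_id <- c(seg_id, rep.int(i, hi - lo + 1L))
  }
  bip$data <- bip$data[idx, , drop = FALSE]
  bip$time_s <- (idx - 1L) / bip$fs
  bip$segment <- seg_id
  bip$n2_segments <- segments
  bip
}

#' Read an N2 / bad-channel sidecar table
#'
#' The sidecar CSV carries either N2 segments (`subject_id, start_s, end_s`)
#' or bad derivations (`subject_id, derivation`).
#'
#' @param path CSV path.
#' @param subject_id optional filter.
#' @return data frame.
#' @export
read_sidecar <- function(path, subject_id = NULL) {
  assert_that(file.exists(path), "io", sprintf("cannot open '%s'", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(subject_id)) x <- x[x$subject_id == subject_id, , drop = FALSE]
  x
}
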