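## Minimal EDF / EDF+ input and output.
##
## EDF stores 16-bit integers in fixed-duration data records, with an ASCII
## header describing per-signal scaling. Annotations (EDF+) travel in a
## dedicated "EDF Annotations" signal holding time-stamped annotation lists
## (TALs). Only the features needed for clinical sleep-EEG exports are
## implemented: one sampling rate per ordinary signal, physical units in
## microvolts, and TAL events with onset, optional duration, and a label.

EDF_HEADER <- 256L

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  pad_field(s, width)
}

#' Write a recording to an EDF(+) file
#'
#' Signals are quantized to 16-bit integers over a symmetric physical range
#' covering the data. Annotations, if present, are written to an
#' `EDF Annotations` signal (making the file EDF+C).
#'
#' @param rec a [raw_recording()].
#' @param path output file path.
#' @param physical_max physical range bound in microvolts; defaults to a
#'   power-of-ten range covering the data.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_max = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  assert_that(abs(fs - round(fs)) < 1e-9, "format",
              "EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  data <- rec$data
  ns <- ncol(data)
  n_rec <- ceiling(nrow(data) / fs)
  if (nrow(data) < n_rec * fs) {
    data <- rbind(data, matrix(0, n_rec * fs - nrow(data), ns))
  }
  if (is.null(physical_max)) {
    m <- max(1, max(abs(data)))
    physical_max <- 10^ceiling(log10(m))
  }
  has_ann <- nrow(rec$annotations) > 0
  ann_raw <- list()
  ann_spr <- 0L
  if (has_ann) {
    ann_raw <- edf_annotation_records(rec$annotations, n_rec)
    ann_spr <- as.integer(ceiling(max(lengths(ann_raw)) / 2) + 1L)
  }
  ns_total <- ns + as.integer(has_ann)
  header_bytes <- EDF_HEADER + 256L * ns_total

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(pad_field("0", 8))
  wr(pad_field(rec$subject_id, 80))
  wr(pad_field(paste("Startdate 01-JAN-2020", rec$subject_id), 80))
  wr(pad_field("01.01.20", 8))
  wr(pad_field("00.00.00", 8))
  wr(num_field(header_bytes, 8))
  wr(pad_field(if (has_ann) "EDF+C" else "", 44))
  wr(num_field(n_rec, 8))
  wr(num_field(1, 8))
  wr(num_field(ns_total, 4))

  labels <- c(colnames(data), if (has_ann) "EDF Annotations")
  for (lab in labels) wr(pad_field(lab, 16))
  for (i in seq_len(ns_total)) wr(pad_field("", 80))
  for (i in seq_len(ns_total))
    wr(pad_field(if (i <= ns) "uV" else "", 8))
  for (i in seq_len(ns_total))
    wr(num_field(if (i <= ns) -physical_max else -1, 8))
  for (i in seq_len(ns_total))
    wr(num_field(if (i <= ns) physical_max else 1, 8))
  for (i in seq_len(ns_total)) wr(num_field(-32768, 8))
  for (i in seq_len(ns_total)) wr(num_field(32767, 8))
  for (i in seq_len(ns_total)) wr(pad_field("", 80))
  for (i in seq_len(ns_total))
    wr(num_field(if (i <= ns) fs else ann_spr, 8))
  for (i in seq_len(ns_total)) wr(pad_field("", 32))

  scale <- 65535 / (2 * physical_max)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(ns)) {
      dig <- round((data[idx, j] + physical_max) * scale) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
    if (has_ann) {
      bytes <- ann_raw[[r]]
      bytes <- c(bytes, raw(2L * ann_spr - length(bytes)))
      writeBin(bytes, con)
    }
  }
  invisible(path)
}

## One TAL byte stream per data record: the mandatory record-time TAL, plus
## any annotation whose onset falls inside that record. TALs are terminated
## by a nul byte, which cannot appear in an R string, so the streams are
## assembled as raw vectors.
edf_annotation_records <- function(ann, n_rec) {
  x14 <- "\x14"; x15 <- "\x15"
  nul <- as.raw(0)
  lapply(seq_len(n_rec), function(r) {
    t0 <- r - 1L
    bytes <- c(charToRaw(sprintf("+%d%s%s", t0, x14, x14)), nul)
    sel <- which(ann$start_s >= t0 & ann$start_s < t0 + 1)
    for (i in sel) {
      dur <- ann$end_s[i] - ann$start_s[i]
      bytes <- c(bytes,
                 charToRaw(sprintf("+%.6g%s%.6g%s%s%s",
                                   ann$start_s[i], x15, dur, x14,
                                   ann$label[i], x14)),
                 nul)
    }
    bytes
  })
}

#' Read an EDF(+) file
#'
#' @param path path to an EDF file.
#' @param require character vector of electrode labels that must be present
#'   (matched case-insensitively after stripping reference suffixes), or
#'   `NULL` to accept any channel set.
#' @return a [raw_recording()]; EDF+ annotations, if present, are parsed into
#'   the `annotations` field.
#' @export
read_edf <- function(path, require = standard_electrodes()) {
  assert_that(file.exists(path), "io", sprintf("cannot open '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  version <- rd(8)
  assert_that(identical(version, "0"), "io",
              sprintf("'%s' is not an EDF file", path))
  subject_id <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  assert_that(!is.na(ns) && ns > 0, "io", "corrupt EDF header")

  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  n_samp <- spr * n_rec
  sig <- lapply(sig_idx, function(j) numeric(n_samp[j]))
  names(sig) <- labels[sig_idx]
  ann_bytes <- raw(0)

  offset <- cumsum(c(0L, 2L * spr))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      if (is_ann[j]) {
        ann_bytes <- c(ann_bytes, readBin(con, "raw", 2L * spr[j]))
      } else {
        dig <- readBin(con, "integer", spr[j], size = 2L, endian = "little")
        k <- match(j, sig_idx)
        g <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
        sig[[k]][((r - 1L) * spr[j] + 1L):(r * spr[j])] <-
          (dig - dig_min[j]) * g + phys_min[j]
      }
    }
  }

  fs_all <- spr[sig_idx] / rec_dur
  req_pos <- match_electrodes(labels[sig_idx], require, error = TRUE)
  if (length(req_pos)) {
    assert_that(length(unique(fs_all[req_pos])) == 1L, "format",
                "required channels have mixed sampling rates")
  }
  fs <- if (length(req_pos)) fs_all[req_pos[1]] else fs_all[1]
  keep <- which(fs_all == fs)
  data <- do.call(cbind, sig[keep])
  colnames(data) <- labels[sig_idx][keep]

  ann <- parse_tal(ann_bytes)
  raw_recording(data = data, fs = fs, subject_id = subject_id,
                annotations = ann)
}

## Parse a stream of TALs into a data frame (label, start_s, end_s).
## Record-keeping TALs (empty label) are dropped.
parse_tal <- function(bytes) {
  empty <- data.frame(label = character(0), start_s = numeric(0),
                      end_s = numeric(0), stringsAsFactors = FALSE)
  if (!length(bytes)) return(empty)
  txt <- rawToChar(bytes[bytes != as.raw(0)])
  ## Simple parse: split the full text on the TAL field separator.
  pieces <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
  out <- empty
  i <- 1L
  while (i <= length(pieces)) {
    head <- pieces[i]
    if (grepl("^[+-][0-9.]+(\x15[0-9.]+)?$", head)) {
      od <- strsplit(head, "\x15", fixed = TRUE)[[1]]
      onset <- as.numeric(od[1])
      dur <- if (length(od) > 1) as.numeric(od[2]) else 0
      j <- i + 1L
      while (j <= length(pieces) &&
             !grepl("^[+-][0-9.]+(\x15[0-9.]+)?$", pieces[j])) {
        lab <- pieces[j]
        if (nzchar(lab)) {
          out <- rbind(out, data.frame(label = lab, start_s = onset,
                                       end_s = onset + dur,
                                       stringsAsFactors = FALSE))
        }
        j <- j + 1L
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  out
}
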