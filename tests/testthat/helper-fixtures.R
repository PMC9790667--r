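## Fixture builders shared across test files. Everything is generated in
## code at test time; no stored data.

## A short subject (340 s -> 320 s of N2) for unit-level pipeline tests.
quick_spec <- function(subject_id = "Q01", lesion_side = "left",
                       asymmetry = c(CO = 1), seed = 1, duration_s = 340,
                       ...) {
  subject_spec(subject_id = subject_id, lesion_side = lesion_side,
               asymmetry = asymmetry, seed = seed, duration_s = duration_s,
               ...)
}

## Referential recording with 1/f background on all ten electrodes plus
## bursts added to named electrodes: bursts is a data frame with columns
## electrode, t0, dur, freq, amp.
burst_recording <- function(duration_s = 320, fs = 256, noise_rms = 5,
                            bursts = NULL, seed = 99, subject_id = "B01") {
  n <- duration_s * fs
  chans <- standard_electrodes()
  data <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  for (j in seq_along(chans)) {
    data[, j] <- synth_background(duration_s, fs, 1.5, noise_rms,
                                  seed = seed * 100 + j)
  }
  if (!is.null(bursts)) {
    for (i in seq_len(nrow(bursts))) {
      w <- synth_spindle(bursts$freq[i], bursts$dur[i], bursts$amp[i], fs)
      i0 <- round(bursts$t0[i] * fs) + 1L
      j <- match(bursts$electrode[i], chans)
      data[i0:(i0 + length(w) - 1L), j] <- data[i0:(i0 + length(w) - 1L), j] + w
    }
  }
  ann <- data.frame(label = "N2", start_s = 0, end_s = duration_s)
  raw_recording(data, fs, subject_id, annotations = ann)
}

## Bipolar N2 recording straight from a burst_recording.
burst_bipolar <- function(...) {
  extract_n2(burst_recording(...))
}

## Exhaustive-permutation oracle for the two-sided Mann-Whitney p-value:
## fraction of equally likely group assignments whose U deviates from
## n1*n2/2 at least as much as observed.
mw_enumeration_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a); N <- length(x)
  r <- rank(x)
  mu <- n1 * (N - n1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  combs <- utils::combn(N, n1)
  U_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(U_all - mu) >= obs - 1e-9)
}

## Concordant-pair oracle for the AUC (orientation: lower score = positive).
auc_pair_oracle <- function(scores, labels) {
  s <- -scores
  pos <- s[as.logical(labels)]
  neg <- s[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

## Match detected events to ground-truth intervals on one derivation
## (overlap criterion: intervals intersect). Returns indices of the truth
## row matched by each detection (NA if none).
match_events <- function(det_onset, det_offset, tr_onset, tr_offset) {
  vapply(seq_along(det_onset), function(i) {
    hit <- which(det_onset[i] < tr_offset & det_offset[i] > tr_onset)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}
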