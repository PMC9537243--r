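# Beat delineation and intra-beat feature extraction.
#
# Systolic peaks are located from runs of high positive slope (the systolic
# upstroke), which is robust to slow baseline wander: the wander's slope is
# small compared with the upstroke's.  Each beat's end trough is the global
# minimum between consecutive peaks, and the beat is indexed by its systolic
# peak.  The diastolic transit time (DTT) of beat i is the interval from its
# systolic peak to the trough that terminates it.

#' Delineate beats in a pulse recording
#'
#' Detects systolic peaks, diastolic troughs and dicrotic notches, and
#' computes per-beat intra-beat features: diastolic transit time (DTT),
#' contractility (maximum first derivative of the systolic upstroke),
#' sensor pulse pressure, inter-beat interval and heart rate.
#'
#' The derivative is computed by central differences after a short moving
#' average (default 15 ms) — raw differences amplify sensor noise.  Equal
#' height maxima are resolved to the earliest sample.  Fiducials carry
#' sample resolution (<= 10 ms at `fs >= 100` Hz); no sub-sample refinement
#' is applied.
#'
#' @param rec a [waveform_recording()] of at least 2 s at `fs >= 100` Hz.
#' @param min_hr_bpm,max_hr_bpm plausible heart-rate range; inter-peak
#'   intervals outside `[60/max_hr, 60/min_hr]` mark beats invalid.
#' @param smooth_s moving-average width in seconds used before
#'   differentiation.
#' @return A `beat_feature_table` data frame, one row per beat, columns:
#'   `beat`, `onset_t`, `peak_t`, `notch_t`, `end_t` (s); `onset_v`,
#'   `peak_v`, `end_v` (signal units); `dtt_s`, `ibi_s` (s); `c_slope`
#'   (units/s); `pp_s` (units); `hr_bpm`; `valid` (logical).  Sample indices
#'   are kept in `onset_idx`, `peak_idx`, `end_idx`.  Empty (0-row) table
#'   with a warning when no beats are detectable.
#' @export
delineate_beats <- function(rec, min_hr_bpm = 40, max_hr_bpm = 180,
                            smooth_s = 0.015) {
  stopifnot(inherits(rec, "waveform_recording"))
  fs <- rec$fs
  x <- rec$samples
  n <- length(x)
  if (n / fs < 2) stop("recording must be at least 2 s long")
  if (fs < 100) stop("sampling rate must be >= 100 Hz")
  if (anyNA(x) || any(!is.finite(x))) stop("samples must be finite")

  k <- max(1L, round(smooth_s * fs))
  xs <- moving_average(x, k)
  d <- central_diff(xs, fs)

  empty <- empty_beat_table()
  if (diff(range(x)) <= .Machine$double.eps * 100) {
    warning("no detectable beats (constant signal)")
    return(empty)
  }
  dq <- stats::quantile(d[d > 0], 0.98, names = FALSE)
  if (!length(dq) || !is.finite(dq) || dq <= 0) {
    warning("no detectable beats (no positive slopes)")
    return(empty)
  }
  thr <- 0.35 * dq
  above <- d > thr
  if (!any(above)) {
    warning("no detectable beats (no upstrokes above threshold)")
    return(empty)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  run_end <- ends[r$values]

  # Peak = maximum of the smoothed signal shortly after each upstroke run;
  # which.max takes the earliest sample on ties.
  look <- round(0.3 * fs)
  peaks <- vapply(run_end, function(e) {
    hi <- min(n, e + look)
    e + which.max(xs[e:hi]) - 1L
  }, integer(1L))
  peaks <- sort(unique(peaks))

  # Enforce the physiological minimum inter-peak distance, keeping the
  # taller peak of any too-close pair.
  min_gap <- round(60 / max_hr_bpm * fs)
  if (length(peaks) > 1L) {
    keep <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- keep[length(keep)]
      if (p - last >= min_gap) {
        keep <- c(keep, p)
      } else if (x[p] > x[last]) {
        keep[length(keep)] <- p
      }
    }
    peaks <- keep
  }
  if (length(peaks) < 2L) {
    warning("fewer than two systolic peaks detected")
    return(empty)
  }

  # Refine each peak on the raw signal in a small neighbourhood.
  peaks <- vapply(peaks, function(p) {
    lo <- max(1L, p - 3L)
    hi <- min(n, p + 3L)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1L))

  nbt <- length(peaks) - 1L
  troughs <- vapply(seq_len(nbt), function(i) {
    lo <- peaks[i] + 1L
    hi <- peaks[i + 1L] - 1L
    lo + which.min(x[lo:hi]) - 1L
  }, integer(1L))

  compute_beat_features(rec, peaks = peaks, troughs = troughs,
                        min_hr_bpm = min_hr_bpm, max_hr_bpm = max_hr_bpm,
                        smooth_s = smooth_s)
}

empty_beat_table <- function() {
  out <- data.frame(
    beat = integer(0), onset_t = numeric(0), peak_t = numeric(0),
    notch_t = numeric(0), end_t = numeric(0), onset_v = numeric(0),
    peak_v = numeric(0), end_v = numeric(0), dtt_s = numeric(0),
    c_slope = numeric(0), pp_s = numeric(0), ibi_s = numeric(0),
    hr_bpm = numeric(0), valid = logical(0),
    onset_idx = integer(0), peak_idx = integer(0), end_idx = integer(0))
  class(out) <- c("beat_feature_table", "data.frame")
  out
}

#' Compute intra-beat features from fiducials
#'
#' Given systolic peak and inter-peak trough sample indices, computes the
#' per-beat feature table.  Beat `i` runs from the trough preceding its peak
#' to the trough following it; its DTT is `end_t - peak_t`, its
#' contractility the maximum smoothed first derivative on the upstroke
#' `[onset, peak]`, and its sensor pulse pressure `peak_v - onset_v`.
#' Beats with non-positive DTT, pulse pressure or contractility, or with
#' inter-beat intervals outside the plausible heart-rate band, are flagged
#' invalid (`valid = FALSE`) and excluded downstream.
#'
#' @param rec a [waveform_recording()].
#' @param peaks integer sample indices of systolic peaks (time-ordered).
#' @param troughs integer sample indices of the troughs between consecutive
#'   peaks (`length(peaks) - 1` of them).
#' @param min_hr_bpm,max_hr_bpm plausible heart-rate range.
#' @param smooth_s derivative pre-smoothing width in seconds.
#' @return A `beat_feature_table`; see [delineate_beats()].
#' @export
compute_beat_features <- function(rec, peaks, troughs,
                                  min_hr_bpm = 40, max_hr_bpm = 180,
                                  smooth_s = 0.015) {
  stopifnot(inherits(rec, "waveform_recording"))
  fs <- rec$fs
  x <- rec$samples
  n <- length(x)
  nbt <- length(peaks) - 1L
  stopifnot(length(troughs) == nbt, nbt >= 1L)
  k <- max(1L, round(smooth_s * fs))
  d <- central_diff(moving_average(x, k), fs)
  idx_t <- function(i) rec$t0 + (i - 1L) / fs

  onset_idx <- integer(nbt)
  notch_t <- rep(NA_real_, nbt)
  c_slope <- numeric(nbt)
  for (i in seq_len(nbt)) {
    onset_idx[i] <- if (i == 1L) {
      lo <- max(1L, peaks[1L] - round(2 * fs))
      lo + which.min(x[lo:(peaks[1L] - 1L)]) - 1L
    } else {
      troughs[i - 1L]
    }
    up <- onset_idx[i]:peaks[i]
    c_slope[i] <- max(d[up])
    notch_t[i] <- find_notch(x, peaks[i], troughs[i], fs, rec$t0)
  }
  peak_i <- peaks[seq_len(nbt)]
  end_i <- troughs
  dtt <- (end_i - peak_i) / fs
  ibi <- diff(peaks) / fs
  pp <- x[peak_i] - x[onset_idx]
  valid <- dtt > 0 & pp > 0 & c_slope > 0 &
    ibi >= 60 / max_hr_bpm & ibi <= 60 / min_hr_bpm

  out <- data.frame(
    beat = seq_len(nbt),
    onset_t = idx_t(onset_idx), peak_t = idx_t(peak_i),
    notch_t = notch_t, end_t = idx_t(end_i),
    onset_v = x[onset_idx], peak_v = x[peak_i], end_v = x[end_i],
    dtt_s = dtt, c_slope = c_slope, pp_s = pp, ibi_s = ibi,
    hr_bpm = 60 / ibi, valid = valid,
    onset_idx = onset_idx, peak_idx = peak_i, end_idx = end_i)
  class(out) <- c("beat_feature_table", "data.frame")
  out
}

# Dicrotic notch: the most prominent local minimum of the signal strictly
# between the systolic peak and the end trough; NA when the decay is
# monotone.
find_notch <- function(x, peak_i, end_i, fs, t0) {
  if (end_i - peak_i < 5L) return(NA_real_)
  seg <- x[peak_i:end_i]
  m <- length(seg)
  interior <- 2:(m - 1L)
  is_min <- seg[interior] < seg[interior - 1L] & seg[interior] <= seg[interior + 1L]
  cand <- interior[is_min]
  if (!length(cand)) return(NA_real_)
  prom <- vapply(cand, function(j) {
    min(max(seg[1:j]), max(seg[j:m])) - seg[j]
  }, numeric(1L))
  j <- cand[which.max(prom)]
  t0 + (peak_i + j - 2L) / fs
}

#' Serialize a beat feature table to CSV
#'
#' @param beats a `beat_feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beat_table <- function(beats, path) {
  utils::write.csv(as.data.frame(beats), path, row.names = FALSE)
  invisible(path)
}
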