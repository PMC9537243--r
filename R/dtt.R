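# The core estimation engine: cuff-anchored calibration, beat-to-beat DBP
# from the diastolic transit time (DTT) and contractility, empirical
# baseline-wander modelling, and corrected SBP/DBP/MAP/HR extraction.
#
# Model: with an initial cuff reading (SBP0, DBP0, PP0 = SBP0 - DBP0),
#
#   eDBP(i) = SBP0 - m0 * DTT(i) * (C(i)/C0)^(-1)
#
# where m0 [mmHg/s] is the calibration factor averaged over the first five
# beats,
#
#   m0 = (1/5) * sum_i  (PP0 / PP_s(i)) * (SBP_s(i) - DBP_s(i+1)) / DTT(i),
#
# PP_s, SBP_s, DBP_s are sensor-unit pulse pressure, peak value and trough
# value, and DBP_s(i+1) is the trough terminating beat i (the trough that
# follows peak i — the same trough that defines DTT(i); whether it is
# labelled beat i or i+1 is a bookkeeping convention with no numerical
# consequence).  Because eDBP is built from intra-beat quantities that an
# additive within-beat-constant offset cannot touch, the difference between
# raw trough pressure and eDBP estimates the baseline wander beat by beat.

#' Initial cuff calibration measurement
#'
#' @param sbp,dbp cuff systolic and diastolic pressures in mmHg
#'   (`sbp > dbp > 0`).
#' @param t_cal time of the cuff measurement in seconds.
#' @return A `cuff_calibration` list with `SBP0`, `DBP0`, `PP0`, `t_cal`.
#' @export
cuff_calibration <- function(sbp, dbp, t_cal = 0) {
  if (!(sbp > dbp && dbp > 0)) stop("cuff requires SBP > DBP > 0")
  structure(list(SBP0 = sbp, DBP0 = dbp, PP0 = sbp - dbp, t_cal = t_cal),
            class = "cuff_calibration")
}

#' Calibrate the conversion factor m0 from the first beats
#'
#' Averages the per-beat factor over the first `n` valid beats and anchors
#' the raw-to-pressure affine map: `gain = PP0 / mean(PP_s)` and `offset`
#' chosen so the mean of the first-`n` end-trough values maps exactly to
#' `DBP0`.  This anchoring makes the calibration closure exact: on a
#' stationary drift-free recording the mean eDBP of the calibration beats
#' reproduces `DBP0`.
#'
#' @param beats a `beat_feature_table`.
#' @param cuff a [cuff_calibration()].
#' @param n number of calibration beats (default 5).
#' @param feature `"dtt"` (diastolic transit time) or `"stt"` (slope
#'   transit time `PP_s/C`, the comparator feature).
#' @return A `calibration_state` list: `m0` (mmHg/s), `C0` (units/s),
#'   `gain` (mmHg/unit), `offset` (mmHg), `n_cal_beats`, `feature`,
#'   `cal_beats` (row indices used).
#' @export
calibrate_m0 <- function(beats, cuff, n = 5L, feature = c("dtt", "stt")) {
  feature <- match.arg(feature)
  stopifnot(inherits(cuff, "cuff_calibration"))
  if (n < 1L) stop("need at least one calibration beat")
  idx <- which(beats$valid)
  if (length(idx) < n) {
    stop(sprintf("fewer than %d valid beats available for calibration", n))
  }
  idx <- idx[seq_len(n)]
  tf <- transit_feature(beats, feature)[idx]
  pp <- beats$pp_s[idx]
  dp <- beats$peak_v[idx] - beats$end_v[idx]
  if (any(tf <= 0)) stop("calibration beat with non-positive transit feature")
  if (any(pp <= 0)) stop("calibration beat with non-positive pulse pressure")
  m0 <- mean((cuff$PP0 / pp) * dp / tf)
  gain <- cuff$PP0 / mean(pp)
  offset <- cuff$DBP0 - gain * mean(beats$end_v[idx])
  structure(
    list(m0 = m0, C0 = mean(beats$c_slope[idx]), gain = gain,
         offset = offset, n_cal_beats = n, feature = feature,
         cal_beats = idx),
    class = "calibration_state")
}

transit_feature <- function(beats, feature) {
  if (feature == "dtt") beats$dtt_s else beats$pp_s / beats$c_slope
}

#' Estimate beat-to-beat diastolic pressure from intra-beat features
#'
#' `eDBP(i) = SBP0 - m0 * DTT(i) * (C(i)/C0)^(-1)`; with an `"stt"`
#' calibration the slope transit time replaces DTT.  The contractility
#' ratio is clamped to `[0.25, 4]` to bound the influence of derivative
#' noise on single beats; invalid beats yield `NA`.
#'
#' @param beats a `beat_feature_table`.
#' @param cal a `calibration_state` from [calibrate_m0()].
#' @param cuff the [cuff_calibration()] used for `cal`.
#' @return Numeric vector of estimated DBP (mmHg), one value per beat.
#' @export
estimate_dbp <- function(beats, cal, cuff) {
  stopifnot(inherits(cal, "calibration_state"),
            inherits(cuff, "cuff_calibration"))
  tf <- transit_feature(beats, cal$feature)
  ratio <- clamp(beats$c_slope / cal$C0, 0.25, 4)
  e <- cuff$SBP0 - cal$m0 * tf / ratio
  e[!beats$valid | beats$c_slope <= 0] <- NA_real_
  e
}

#' Transform a sensor-unit recording into pressure units
#'
#' Applies the affine map fixed at calibration: `out = gain * raw + offset`
#' (mmHg).  A recording already in mmHg is returned unchanged with a
#' warning.
#'
#' @param rec a [waveform_recording()] in sensor units.
#' @param cal a `calibration_state`.
#' @return A `waveform_recording` in mmHg.
#' @export
to_pressure_units <- function(rec, cal) {
  stopifnot(inherits(rec, "waveform_recording"),
            inherits(cal, "calibration_state"))
  if (rec$units == "mmHg") {
    warning("recording is already in mmHg; returning it unchanged")
    return(rec)
  }
  waveform_recording(cal$gain * rec$samples + cal$offset, fs = rec$fs,
                     t0 = rec$t0, channel = rec$channel, units = "mmHg")
}

#' Centred moving median with shrinking edge windows
#'
#' The window covers `floor((w-1)/2)` points to the left of each position
#' and the remainder to the right, shrinking near the edges so the output
#' has the length of the input.  Window 1 is the identity.
#'
#' @param x numeric series.
#' @param window window length in points (default 30).
#' @return Numeric vector of the same length as `x`.
#' @export
moving_median <- function(x, window = 30L) {
  if (window < 1L) stop("window must be >= 1")
  n <- length(x)
  if (!n) return(numeric(0))
  if (window == 1L) return(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - half_lo):min(n, i + half_hi)])
  }, numeric(1L))
}

#' Empirical baseline-wander estimate
#'
#' The raw per-beat offset is the difference between the trough pressure
#' read from the raw (pressure-unit) signal and the intra-beat DBP
#' estimate; because eDBP is immune to additive baseline offsets, this
#' difference *is* the wander sampled at each beat.  A 30-point moving
#' median smooths it, rejecting outlier beats.
#'
#' @param raw_dbp_mmHg per-beat raw trough pressure (mmHg).
#' @param edbp per-beat estimated DBP (mmHg), same length.
#' @param window moving-median window in beats (default 30).
#' @return A `baseline_estimate` list with `raw_offset` and
#'   `smoothed_offset` (mmHg, one value per beat).
#' @export
baseline_offset <- function(raw_dbp_mmHg, edbp, window = 30L) {
  if (length(raw_dbp_mmHg) != length(edbp)) {
    stop("raw DBP and eDBP series must have equal length")
  }
  raw <- raw_dbp_mmHg - edbp
  filled <- raw
  if (anyNA(filled) && !all(is.na(filled))) {
    ok <- which(!is.na(filled))
    filled <- stats::approx(ok, filled[ok], xout = seq_along(filled),
                            rule = 2)$y
  }
  structure(list(raw_offset = raw,
                 smoothed_offset = moving_median(filled, window)),
            class = "baseline_estimate")
}

#' Subtract the modelled baseline and extract corrected BP
#'
#' The smoothed per-beat offsets, anchored at each beat's end trough, are
#' linearly interpolated to every sample and subtracted from the
#' pressure-unit recording (step interpolation would create discontinuities
#' inside beats).  From the corrected signal each beat contributes
#' `SBP` (maximum over the beat), `DBP` (minimum between its systolic peak
#' and the next), `MAP = DBP + (SBP - DBP)/3` and `HR = 60/ibi`.  Beats
#' whose SBP or DBP deviates from its own 30-point moving median by more
#' than `outlier_mmHg` are marked excluded, as are beats flagged invalid at
#' delineation.
#'
#' @param rec_mmHg pressure-unit [waveform_recording()].
#' @param beats the `beat_feature_table` for the recording.
#' @param baseline a `baseline_estimate` from [baseline_offset()].
#' @param outlier_mmHg exclusion threshold around the moving median
#'   (default 10 mmHg).
#' @param retained optional logical per-beat mask (e.g. from QC) ANDed into
#'   the exclusion flag.
#' @return A `bp_series` data frame: `t` (systolic peak time), `SBP`,
#'   `DBP`, `MAP` (mmHg), `HR` (bpm), `eDBP` (mmHg, when supplied via
#'   `attr(baseline, "edbp")`), `excluded`.  The corrected waveform is
#'   attached as attribute `"corrected"`.
#' @export
correct_and_extract <- function(rec_mmHg, beats, baseline,
                                outlier_mmHg = 10, retained = NULL) {
  stopifnot(inherits(rec_mmHg, "waveform_recording"),
            inherits(baseline, "baseline_estimate"))
  if (rec_mmHg$units != "mmHg") stop("recording must be in mmHg")
  nb <- nrow(beats)
  if (!nb) {
    warning("no beats to extract")
    return(empty_bp_series())
  }
  tt <- rec_times(rec_mmHg)
  off <- stats::approx(beats$end_t, baseline$smoothed_offset, xout = tt,
                       rule = 2)$y
  corrected <- rec_mmHg$samples - off

  n <- length(corrected)
  sbp <- dbp <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    span <- beats$onset_idx[i]:beats$end_idx[i]
    sbp[i] <- max(corrected[span])
    hi <- if (i < nb) beats$peak_idx[i + 1L] - 1L else beats$end_idx[i]
    dbp[i] <- min(corrected[beats$peak_idx[i]:min(hi, n)])
  }
  map <- dbp + (sbp - dbp) / 3
  hr <- 60 / beats$ibi_s

  excl <- !beats$valid
  excl <- excl | abs(sbp - moving_median(sbp, 30L)) > outlier_mmHg
  excl <- excl | abs(dbp - moving_median(dbp, 30L)) > outlier_mmHg
  if (!is.null(retained)) excl <- excl | !retained
  edbp <- attr(baseline, "edbp") %||% rep(NA_real_, nb)

  out <- data.frame(t = beats$peak_t, SBP = sbp, DBP = dbp, MAP = map,
                    HR = hr, eDBP = edbp, excluded = excl)
  class(out) <- c("bp_series", "data.frame")
  attr(out, "corrected") <- waveform_recording(
    corrected, fs = rec_mmHg$fs, t0 = rec_mmHg$t0,
    channel = rec_mmHg$channel, units = "mmHg")
  if (all(excl)) warning("all beats excluded")
  out
}

empty_bp_series <- function() {
  out <- data.frame(t = numeric(0), SBP = numeric(0), DBP = numeric(0),
                    MAP = numeric(0), HR = numeric(0), eDBP = numeric(0),
                    excluded = logical(0))
  class(out) <- c("bp_series", "data.frame")
  out
}

#' Full single-sensor DTT estimation pipeline
#'
#' Convenience wrapper running delineation, calibration from the first
#' `n_cal` beats, intra-beat DBP estimation, baseline-wander modelling and
#' corrected BP extraction on one sensor recording, using a single initial
#' cuff measurement and no recalibration.
#'
#' @param rec sensor-unit [waveform_recording()].
#' @param cuff a [cuff_calibration()].
#' @param n_cal number of calibration beats (default 5).
#' @param feature `"dtt"` or `"stt"` (the comparator feature).
#' @param min_hr_bpm,max_hr_bpm heart-rate band for delineation.
#' @param median_window moving-median window in beats (default 30).
#' @param outlier_mmHg outlier exclusion threshold (default 10 mmHg).
#' @param retained optional per-beat QC mask.
#' @return A list: `bp` (`bp_series`), `beats`, `cal`, `baseline`.
#' @export
dtt_bp <- function(rec, cuff, n_cal = 5L, feature = "dtt",
                   min_hr_bpm = 40, max_hr_bpm = 180,
                   median_window = 30L, outlier_mmHg = 10,
                   retained = NULL) {
  beats <- delineate_beats(rec, min_hr_bpm = min_hr_bpm,
                           max_hr_bpm = max_hr_bpm)
  if (!nrow(beats)) {
    warning("no beats detected; returning empty result")
    return(list(bp = empty_bp_series(), beats = beats, cal = NULL,
                baseline = NULL))
  }
  cal <- calibrate_m0(beats, cuff, n = n_cal, feature = feature)
  edbp <- estimate_dbp(beats, cal, cuff)
  rec_p <- to_pressure_units(rec, cal)
  raw_dbp <- cal$gain * beats$end_v + cal$offset
  baseline <- baseline_offset(raw_dbp, edbp, window = median_window)
  attr(baseline, "edbp") <- edbp
  bp <- correct_and_extract(rec_p, beats, baseline,
                            outlier_mmHg = outlier_mmHg, retained = retained)
  list(bp = bp, beats = beats, cal = cal, baseline = baseline)
}

#' Write a BP series to CSV
#'
#' @param bp a `bp_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bp_series <- function(bp, path) {
  utils::write.csv(as.data.frame(bp), path, row.names = FALSE)
  invisible(path)
}
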