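# Signal-quality control: continuity filtering and detection of
# applanation-pressure deviations via paired contractility regressions.

#' Retain only beats in sufficiently long continuous runs
#'
#' Beats are kept only when they lie in a maximal run of consecutive valid
#' beats spanning at least `min_len_s` seconds (onset of the first beat in
#' the run to end trough of the last).  Shorter runs are excluded entirely,
#' mirroring the requirement that usable segments contain at least 30 s of
#' continuous well-formed waveforms.
#'
#' @param beats a `beat_feature_table` (time-ordered).
#' @param min_len_s minimum run span in seconds (default 30).
#' @return Logical vector, one element per beat.
#' @export
continuity_filter <- function(beats, min_len_s = 30) {
  nb <- nrow(beats)
  if (!nb) return(logical(0))
  retained <- logical(nb)
  r <- rle(beats$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i1 <- starts[j]; i2 <- ends[j]
    span <- beats$end_t[i2] - beats$onset_t[i1]
    if (span >= min_len_s) retained[i1:i2] <- TRUE
  }
  retained
}

#' Detect applanation-pressure deviations from paired contractility trends
#'
#' Changes in sensor contact (applanation) pressure alter waveform
#' amplitude, and hence contractility, on the affected sensor only.  Over a
#' sliding window, each channel's per-beat contractility is normalised by
#' its own window mean and regressed on time; the two slopes are compared
#' with the interaction t-test of the pooled regression
#' (`lm(c_norm ~ t * channel)`).  A window is flagged when the slopes
#' differ at level `alpha`, and beats falling in any flagged window are
#' excluded from the retained mask.
#'
#' Mean-normalisation makes the test invariant to constant gain on either
#' channel: only genuine within-window trend differences flag.
#'
#' @param sensor_beats,ref_beats `beat_feature_table`s from the test sensor
#'   and the reference channel; must overlap in time.
#' @param window_s sliding-window length in seconds (default 30).
#' @param step_s window step in seconds (default 5).
#' @param alpha significance level (default 0.05).
#' @param min_pairs minimum paired beats per window; windows with fewer are
#'   skipped with a warning.
#' @return A `qc_report` list: `windows` (data frame with `t_start`,
#'   `t_end`, `n_pairs`, `p_value`, `flagged`, `skipped`), `retained_mask`
#'   (per sensor beat), and `criteria_log`.
#' @export
detect_applanation_deviation <- function(sensor_beats, ref_beats,
                                         window_s = 30, step_s = 5,
                                         alpha = 0.05, min_pairs = 10L) {
  stopifnot(nrow(sensor_beats) > 0L, nrow(ref_beats) > 0L)
  ts <- sensor_beats$peak_t
  tr <- ref_beats$peak_t
  tol <- 0.5 * stats::median(ref_beats$ibi_s, na.rm = TRUE)
  j <- vapply(ts, function(t) which.min(abs(tr - t)), integer(1L))
  ok <- abs(tr[j] - ts) <= tol
  if (!any(ok)) stop("sensor and reference beat tables do not overlap in time")
  pair_t <- ts[ok]
  cs <- sensor_beats$c_slope[ok]
  cr <- ref_beats$c_slope[j[ok]]

  t_lo <- min(pair_t)
  t_hi <- max(pair_t)
  starts <- seq(t_lo, max(t_lo, t_hi - window_s), by = step_s)
  win <- lapply(starts, function(w0) {
    sel <- pair_t >= w0 & pair_t < w0 + window_s
    np <- sum(sel)
    if (np < min_pairs) {
      return(data.frame(t_start = w0, t_end = w0 + window_s, n_pairs = np,
                        p_value = NA_real_, flagged = FALSE, skipped = TRUE))
    }
    p <- slope_difference_p(pair_t[sel], cs[sel], cr[sel])
    data.frame(t_start = w0, t_end = w0 + window_s, n_pairs = np,
               p_value = p, flagged = is.finite(p) && p < alpha,
               skipped = FALSE)
  })
  windows <- do.call(rbind, win)
  n_skip <- sum(windows$skipped)
  if (n_skip) {
    warning(sprintf("%d window(s) skipped (fewer than %d paired beats)",
                    n_skip, min_pairs))
  }
  retained <- rep(TRUE, nrow(sensor_beats))
  for (i in which(windows$flagged)) {
    retained[ts >= windows$t_start[i] & ts < windows$t_end[i]] <- FALSE
  }
  structure(
    list(windows = windows, retained_mask = retained,
         criteria_log = sprintf(
           "%d/%d windows flagged (alpha=%g, window=%gs, step=%gs), %d skipped",
           sum(windows$flagged), nrow(windows), alpha, window_s, step_s,
           n_skip)),
    class = "qc_report")
}

#' Compare two within-window contractility trends
#'
#' Each series is normalised by its own mean, both are regressed on time,
#' and the p-value of the slope difference is taken from the interaction
#' term of the pooled model `lm(y ~ t * channel)` (pooled residual
#' variance).  Exposed for direct use and simulation studies.
#'
#' @param t shared time points (seconds).
#' @param c_a,c_b contractility values of the two channels at `t`.
#' @return Two-sided p-value for equality of normalised slopes.
#' @export
slope_difference_p <- function(t, c_a, c_b) {
  ya <- c_a / mean(c_a)
  yb <- c_b / mean(c_b)
  df <- data.frame(y = c(ya, yb), t = c(t, t),
                   ch = rep(c("a", "b"), each = length(t)))
  fit <- stats::lm(y ~ t * ch, data = df)
  co <- summary(fit)$coefficients
  row <- grep("^t:ch", rownames(co))
  if (!length(row)) return(NA_real_)
  unname(co[row, 4L])
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$criteria_log, "\n")
  invisible(x)
}

#' Write a QC report to JSON
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    list(windows = report$windows, retained_mask = report$retained_mask,
         criteria_log = report$criteria_log),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
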