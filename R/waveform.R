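#' Construct a uniformly sampled waveform recording
#'
#' The basic container for a continuous pulse signal: a numeric sample
#' vector, its sampling rate, the time of the first sample, the sensor
#' channel kind and a unit flag (`"sensor"` for uncalibrated arbitrary units,
#' `"mmHg"` for pressure).
#'
#' @param samples numeric vector of signal values; must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param channel one of `"cap"`, `"ppg"`, `"aline"`, `"other"`.
#' @param units one of `"sensor"`, `"mmHg"`.
#' @return An object of class `waveform_recording`.
#' @export
waveform_recording <- function(samples, fs, t0 = 0,
                               channel = c("other", "cap", "ppg", "aline"),
                               units = c("sensor", "mmHg")) {
  channel <- match.arg(channel)
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("`samples` must be finite and free of NA")
  }
  structure(
    list(samples = samples, fs = fs, t0 = t0,
         channel = channel, units = units),
    class = "waveform_recording"
  )
}

#' Sample times of a recording
#'
#' @param rec a [waveform_recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
rec_times <- function(rec) {
  rec$t0 + (seq_along(rec$samples) - 1L) / rec$fs
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf(
    "<waveform_recording> %d samples @ %g Hz (%.1f s), channel=%s, units=%s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs, x$channel, x$units))
  invisible(x)
}

#' @export
length.waveform_recording <- function(x) length(x$samples)

#' Write a recording to CSV
#'
#' Two columns, `time_s` and `value`, with a header row.  A JSON sidecar
#' (`<path>.json`) stores the sampling rate, channel and unit flag so the
#' recording round-trips through [read_recording()].
#'
#' @param rec a [waveform_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_recording"))
  df <- data.frame(time_s = rec_times(rec), value = rec$samples)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = rec$fs, t0 = rec$t0, channel = rec$channel,
               units = rec$units)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Expects the format written by [write_recording()]: columns `time_s` and
#' `value`.  Timestamps must be strictly increasing and uniform (maximum
#' jitter below 0.1 sample intervals); missing values are rejected.
#'
#' @param path CSV path.
#' @param channel,units overrides for the channel and unit flags; defaults
#'   come from the JSON sidecar when present.
#' @return A [waveform_recording()].
#' @export
read_recording <- function(path, channel = NULL, units = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("recording CSV must have columns `time_s` and `value`")
  }
  tt <- df$time_s
  if (anyNA(tt) || anyNA(df$value)) stop("recording contains missing values")
  dt <- diff(tt)
  if (any(dt <= 0)) stop("timestamps are not strictly increasing")
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.1 * step) {
    stop("sampling is not uniform (timestamp jitter exceeds 0.1/fs)")
  }
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  waveform_recording(
    df$value, fs = 1 / step, t0 = tt[1L],
    channel = channel %||% (meta$channel %||% "other"),
    units = units %||% (meta$units %||% "sensor"))
}
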