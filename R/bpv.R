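# Beat-to-beat blood-pressure variability over 30-beat windows.

#' Compute beat-to-beat BP variability indices
#'
#' Summarises non-excluded beats over consecutive non-overlapping windows
#' of `window_beats` beats, separately for each requested parameter.  Per
#' window: `SD` (sample standard deviation, mmHg), `COV = SD/mean`
#' (fraction), and `ARV` (average real variability, the mean absolute
#' difference between adjacent beats, mmHg — sensitive to temporal order
#' where SD is not).  Windows whose BP range (max - min of the series being
#' summarised) exceeds `labile_range_mmHg` are flagged labile — such swings
#' reflect hemodynamic interventions rather than intrinsic variability —
#' and are omitted from the recording-level averages.
#'
#' @param bp a `bp_series`.
#' @param window_beats beats per window (default 30); trailing beats that
#'   do not fill a window are dropped.
#' @param labile_range_mmHg labile-window exclusion threshold (default 10).
#' @param params which series to summarise (default SBP and DBP).
#' @return A `bpv_report` list: `windows` (data frame with `param`,
#'   `window`, `t_start`, `t_end`, `n_beats`, `sd`, `cov`, `arv`,
#'   `excluded_labile`) and `summary` (per-parameter means of each index
#'   over non-labile windows, plus window counts).  Empty report with a
#'   warning when no full window exists.
#' @export
compute_bpv <- function(bp, window_beats = 30L, labile_range_mmHg = 10,
                        params = c("SBP", "DBP")) {
  stopifnot(inherits(bp, "bp_series"))
  use <- bp[!bp$excluded, , drop = FALSE]
  n <- nrow(use)
  nw <- n %/% window_beats
  if (nw < 1L) {
    warning("fewer than one full window of beats; empty BPV report")
    return(structure(list(windows = data.frame(), summary = data.frame()),
                     class = "bpv_report"))
  }
  rows <- list()
  for (p in params) {
    v <- use[[p]]
    for (w in seq_len(nw)) {
      i <- ((w - 1L) * window_beats + 1L):(w * window_beats)
      vw <- v[i]
      sdw <- stats::sd(vw)
      rows[[length(rows) + 1L]] <- data.frame(
        param = p, window = w,
        t_start = use$t[i[1L]], t_end = use$t[i[length(i)]],
        n_beats = length(i), sd = sdw, cov = sdw / mean(vw),
        arv = mean(abs(diff(vw))),
        excluded_labile = (max(vw) - min(vw)) > labile_range_mmHg)
    }
  }
  windows <- do.call(rbind, rows)
  keep <- windows[!windows$excluded_labile, , drop = FALSE]
  summary <- do.call(rbind, lapply(params, function(p) {
    kp <- keep[keep$param == p, , drop = FALSE]
    data.frame(param = p, n_windows = sum(windows$param == p),
               n_labile = sum(windows$param == p & windows$excluded_labile),
               mean_sd = mean(kp$sd), mean_cov = mean(kp$cov),
               mean_arv = mean(kp$arv))
  }))
  structure(list(windows = windows, summary = summary), class = "bpv_report")
}

#' @export
print.bpv_report <- function(x, ...) {
  cat("<bpv_report>\n")
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
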