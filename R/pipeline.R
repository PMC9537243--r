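# End-to-end pipeline: configuration validation, stage orchestration and
# file output.  Stage order: delineation -> continuity filter -> paired QC
# (when a reference is available) -> calibration -> estimation -> baseline
# correction -> extraction -> variability -> agreement.

#' Pipeline configuration
#'
#' @param sensor a [waveform_recording()] or path to a recording CSV.
#' @param cuff_sbp,cuff_dbp initial cuff measurement (mmHg).
#' @param reference optional reference recording (or path) in mmHg for QC
#'   and agreement analysis.
#' @param n_cal_beats calibration beats (default 5; must be >= 1).
#' @param median_window moving-median window in beats (default 30).
#' @param outlier_mmHg outlier exclusion threshold (default 10).
#' @param min_run_s continuity-filter minimum run length (default 30 s).
#' @param qc_window_s,qc_step_s,qc_alpha applanation-QC parameters.
#' @param bpv_window_beats,bpv_labile_mmHg variability parameters.
#' @param comparators character vector among `"bf"`, `"dwt"`, `"stt"` to
#'   run alongside the DTT engine (default none).
#' @param out_dir optional output directory; when given, stage outputs are
#'   written as CSV/JSON.
#' @param seed integer seed recorded in the run log.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sensor, cuff_sbp, cuff_dbp, reference = NULL,
                            n_cal_beats = 5L, median_window = 30L,
                            outlier_mmHg = 10, min_run_s = 30,
                            qc_window_s = 30, qc_step_s = 5,
                            qc_alpha = 0.05,
                            bpv_window_beats = 30L, bpv_labile_mmHg = 10,
                            comparators = character(0),
                            out_dir = NULL, seed = 1L) {
  if (n_cal_beats < 1L) stop("n_cal_beats must be >= 1")
  if (median_window < 1L) stop("median_window must be >= 1")
  bad <- setdiff(comparators, c("bf", "dwt", "stt"))
  if (length(bad)) stop("unknown comparators: ", paste(bad, collapse = ", "))
  structure(
    list(sensor = sensor, reference = reference,
         cuff = cuff_calibration(cuff_sbp, cuff_dbp),
         n_cal_beats = as.integer(n_cal_beats),
         median_window = as.integer(median_window),
         outlier_mmHg = outlier_mmHg, min_run_s = min_run_s,
         qc_window_s = qc_window_s, qc_step_s = qc_step_s,
         qc_alpha = qc_alpha,
         bpv_window_beats = as.integer(bpv_window_beats),
         bpv_labile_mmHg = bpv_labile_mmHg,
         comparators = comparators, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

resolve_recording <- function(x, units = NULL) {
  if (inherits(x, "waveform_recording")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_recording(x))
  stop("expected a waveform_recording or a file path")
}

#' Run the full estimation pipeline
#'
#' @param config a [pipeline_config()].
#' @return A list with `bp` (`bp_series`), `beats`, `cal`, `baseline`,
#'   `qc` (`qc_report` or `NULL` in single-sensor mode, where the pairwise
#'   applanation test is not evaluable), `bpv` (`bpv_report`), `agreement`
#'   (`agreement_report` or `NULL`), `comparators` (named list of
#'   comparator `bp_series`), and `log` (stage log with parameters and
#'   exclusion counts).  With `out_dir` set, results are also written to
#'   disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(seed = config$seed,
              params = config[setdiff(names(config),
                                      c("sensor", "reference", "out_dir"))])
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    log$timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    out
  }

  sensor <- stage("read", resolve_recording(config$sensor))
  reference <- if (!is.null(config$reference)) {
    stage("read_reference", resolve_recording(config$reference))
  }

  beats <- stage("delineation", delineate_beats(sensor))
  if (!nrow(beats)) stop("[stage delineation] no beats detected")
  cont <- stage("continuity", continuity_filter(beats, config$min_run_s))
  log$n_beats <- nrow(beats)
  log$n_continuity_excluded <- sum(!cont)

  qc <- NULL
  retained <- cont
  if (!is.null(reference)) {
    ref_beats <- stage("reference_delineation", delineate_beats(reference))
    qc <- stage("applanation_qc", detect_applanation_deviation(
      beats, ref_beats, window_s = config$qc_window_s,
      step_s = config$qc_step_s, alpha = config$qc_alpha))
    retained <- retained & qc$retained_mask
    log$n_qc_excluded <- sum(!qc$retained_mask)
  } else {
    log$qc <- "skipped (single-sensor mode: pairwise test not evaluable)"
  }

  fit <- stage("estimation", dtt_bp(
    sensor, config$cuff, n_cal = config$n_cal_beats,
    median_window = config$median_window,
    outlier_mmHg = config$outlier_mmHg, retained = retained))
  log$n_excluded <- sum(fit$bp$excluded)

  bpv <- stage("variability", compute_bpv(
    fit$bp, window_beats = config$bpv_window_beats,
    labile_range_mmHg = config$bpv_labile_mmHg))

  agreement <- NULL
  if (!is.null(reference)) {
    agreement <- stage("agreement", {
      ref_fit <- extract_reference_bp(reference)
      pairs <- pair_series(fit$bp, ref_fit)
      bland_altman_pearson(pairs)
    })
  } else {
    log$agreement <- "skipped (no reference channel)"
  }

  comp <- list()
  for (m in config$comparators) {
    comp[[m]] <- stage(paste0("comparator_", m), switch(m,
      bf = filter_bp(sensor, config$cuff, "bf")$bp,
      dwt = filter_bp(sensor, config$cuff, "dwt")$bp,
      stt = stt_bp(sensor, config$cuff)$bp))
  }

  res <- list(bp = fit$bp, beats = fit$beats, cal = fit$cal,
              baseline = fit$baseline, qc = qc, bpv = bpv,
              agreement = agreement, comparators = comp, log = log)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  res
}

# Beat-to-beat BP read directly off a pressure-unit reference recording
# (an arterial line needs no calibration or correction).
extract_reference_bp <- function(reference) {
  b <- delineate_beats(reference)
  if (!nrow(b)) stop("no beats detected on the reference channel")
  out <- data.frame(t = b$peak_t, SBP = b$peak_v, DBP = b$end_v,
                    MAP = b$end_v + (b$peak_v - b$end_v) / 3,
                    HR = 60 / b$ibi_s, eDBP = NA_real_,
                    excluded = !b$valid)
  class(out) <- c("bp_series", "data.frame")
  out
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_bp_series(res$bp, p("bp_series.csv"))
  write_beat_table(res$beats, p("beats.csv"))
  if (!is.null(res$qc)) write_qc_report(res$qc, p("qc_report.json"))
  if (nrow(res$bpv$windows %||% data.frame())) {
    utils::write.csv(res$bpv$windows, p("bpv_windows.csv"), row.names = FALSE)
  }
  if (!is.null(res$agreement)) {
    jsonlite::write_json(
      list(n_pairs = res$agreement$n_pairs, table = res$agreement$table),
      p("agreement.json"), auto_unbox = TRUE, digits = NA)
  }
  for (m in names(res$comparators)) {
    write_bp_series(res$comparators[[m]], p(sprintf("bp_series_%s.csv", m)))
  }
  jsonlite::write_json(res$log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(NULL)
}
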