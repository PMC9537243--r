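# Method-agreement statistics between an estimated BP series and a
# reference: beat pairing, percent errors, Pearson correlation,
# Bland-Altman bias and limits of agreement, the AAMI/ISO 81060-2 bound,
# and the Brown-Forsythe variance-equality test for BPV comparison.

#' Pair two beat-indexed BP series by time
#'
#' Each non-excluded estimated beat is matched to the nearest non-excluded
#' reference beat within `max_lag_s`; when several estimated beats claim
#' the same reference beat, the closest wins and the others are dropped.
#' The default tolerance of 0.5 s is half the one-second synchronisation
#' precision of typical clinical clocks, avoiding cross-beat matches at
#' heart rates above 60 bpm.
#'
#' @param est,ref `bp_series` objects with overlapping time spans.
#' @param max_lag_s maximum pairing lag in seconds (default 0.5).
#' @return Data frame with columns `t_est`, `t_ref`, `lag_s` and
#'   `<param>_est` / `<param>_ref` for SBP, DBP, MAP, HR.  The number of
#'   dropped estimated beats is in attribute `n_dropped`.
#' @export
pair_series <- function(est, ref, max_lag_s = 0.5) {
  e <- est[!est$excluded, , drop = FALSE]
  r <- ref[!ref$excluded, , drop = FALSE]
  if (!nrow(e) || !nrow(r)) stop("no non-excluded beats to pair")
  j <- vapply(e$t, function(t) which.min(abs(r$t - t)), integer(1L))
  lag <- e$t - r$t[j]
  ok <- abs(lag) <= max_lag_s
  if (!any(ok)) stop("no beat pairs within the pairing tolerance")
  e <- e[ok, , drop = FALSE]
  j <- j[ok]
  lag <- lag[ok]
  # resolve duplicate claims on the same reference beat: nearest wins
  o <- order(abs(lag))
  keep_first <- !duplicated(j[o])
  sel <- sort(o[keep_first])
  e <- e[sel, , drop = FALSE]
  j <- j[sel]
  out <- data.frame(t_est = e$t, t_ref = r$t[j], lag_s = e$t - r$t[j])
  for (p in c("SBP", "DBP", "MAP", "HR")) {
    out[[paste0(p, "_est")]] <- e[[p]]
    out[[paste0(p, "_ref")]] <- r[[p]][j]
  }
  attr(out, "n_dropped") <- sum(!est$excluded) - nrow(out)
  out
}

#' Per-beat absolute percent errors
#'
#' `100 * |est - ref| / ref` per paired beat and parameter; beats with
#' non-positive reference values are skipped.
#'
#' @param pairs output of [pair_series()].
#' @param params parameters to evaluate.
#' @return Named list of numeric percent-error vectors.
#' @export
percent_error_series <- function(pairs, params = c("SBP", "DBP", "MAP")) {
  out <- lapply(params, function(p) {
    est <- pairs[[paste0(p, "_est")]]
    ref <- pairs[[paste0(p, "_ref")]]
    ok <- ref > 0
    100 * abs(est[ok] - ref[ok]) / ref[ok]
  })
  names(out) <- params
  out
}

#' Pearson correlation and Bland-Altman agreement
#'
#' For each parameter, computes differences `est - ref`, their mean bias
#' and sample SD, limits of agreement at 1 SD (68%) and 1.96 SD (95%),
#' the Pearson correlation of the paired values, mean and SD of the
#' absolute percent error, and the AAMI/ISO 81060-2 verdict
#' (`|mean bias| <= 5` mmHg and `SD < 8` mmHg).
#'
#' @param pairs output of [pair_series()].
#' @param params parameters to evaluate.
#' @return An `agreement_report`: list with `n_pairs` and `table`, a data
#'   frame with one row per parameter (`pearson_r` is `NA` when either
#'   series has zero variance).
#' @export
bland_altman_pearson <- function(pairs, params = c("SBP", "DBP", "MAP", "HR")) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs")
  pct <- percent_error_series(pairs, intersect(params, c("SBP", "DBP", "MAP")))
  rows <- lapply(params, function(p) {
    est <- pairs[[paste0(p, "_est")]]
    ref <- pairs[[paste0(p, "_ref")]]
    d <- est - ref
    bias <- mean(d)
    sdd <- stats::sd(d)
    r <- if (stats::sd(est) > 0 && stats::sd(ref) > 0) {
      stats::cor(est, ref)
    } else {
      NA_real_
    }
    pe <- pct[[p]]
    data.frame(
      param = p, pearson_r = r, mean_bias = bias, sd_diff = sdd,
      loa_68_lo = bias - sdd, loa_68_hi = bias + sdd,
      loa_95_lo = bias - 1.96 * sdd, loa_95_hi = bias + 1.96 * sdd,
      aami_pass = abs(bias) <= 5 && sdd < 8,
      mean_pct_error = if (is.null(pe)) NA_real_ else mean(pe),
      sd_pct_error = if (is.null(pe)) NA_real_ else stats::sd(pe))
  })
  structure(list(n_pairs = nrow(pairs), table = do.call(rbind, rows)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n_pairs = %d\n", x$n_pairs))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Brown-Forsythe test for equality of BP variability
#'
#' The Brown-Forsythe variant of Levene's test: a one-way ANOVA on the
#' absolute deviations from each group's median.  Used to ask whether two
#' sets of windowed BPV values (e.g. window SDs before and after
#' processing) differ in level.
#'
#' @param bpv_a,bpv_b numeric vectors (>= 3 values each), e.g. per-window
#'   SDs from two measurement sets.
#' @param alpha significance level (default 0.05).
#' @return List with `p_value`, `different` (`p < alpha`) and `statistic`
#'   (the F statistic).  Degenerate all-equal input gives `p = 1`.
#' @export
bpv_equivalence_test <- function(bpv_a, bpv_b, alpha = 0.05) {
  stopifnot(length(bpv_a) >= 3L, length(bpv_b) >= 3L)
  z <- c(abs(bpv_a - stats::median(bpv_a)),
         abs(bpv_b - stats::median(bpv_b)))
  if (all(z == 0)) {
    return(list(p_value = 1, different = FALSE, statistic = 0))
  }
  g <- factor(rep(c("a", "b"), c(length(bpv_a), length(bpv_b))))
  tab <- stats::anova(stats::lm(z ~ g))
  p <- tab[["Pr(>F)"]][1L]
  list(p_value = p, different = is.finite(p) && p < alpha,
       statistic = tab[["F value"]][1L])
}
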