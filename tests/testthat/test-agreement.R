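mk_bp <- function(sbp, dbp = sbp - 40, t = seq_along(sbp), hr = 60) {
  out <- data.frame(t = t, SBP = sbp, DBP = dbp,
                    MAP = dbp + (sbp - dbp) / 3, HR = hr,
                    eDBP = NA_real_, excluded = FALSE)
  class(out) <- c("bp_series", "data.frame")
  out
}

test_that("pairing matches beats by time within the tolerance", {
  set.seed(61)
  a <- mk_bp(100 + stats::rnorm(50))
  expect_equal(nrow(pair_series(a, a)), 50)
  expect_equal(pair_series(a, a)$lag_s, rep(0, 50))

  shifted <- a
  shifted$t <- a$t + 0.3
  p <- pair_series(shifted, a)
  expect_equal(nrow(p), 50)
  expect_equal(p$lag_s, rep(0.3, 50), tolerance = 1e-12)

  # a 2 s shift with 1 s beats: nearest-match within 0.5 s silently pairs
  # against the wrong beats (offset by two) and drops the overhang
  far <- a
  far$t <- a$t + 2
  p2 <- pair_series(far, a)
  expect_equal(nrow(p2), 48)
  expect_equal(p2$lag_s, rep(0, 48), tolerance = 1e-12)
  expect_equal(p2$SBP_est, a$SBP[1:48])
  expect_equal(p2$SBP_ref, a$SBP[3:50])
})

test_that("percent errors follow the definition", {
  a <- mk_bp(c(121, 119, 122))
  r <- mk_bp(c(120, 120, 120))
  pe <- percent_error_series(pair_series(a, r))
  expect_equal(mean(pe$SBP), (0.83333333 + 0.83333333 + 1.66666667) / 3,
               tolerance = 1e-7)
  pe0 <- percent_error_series(pair_series(a, a))
  expect_equal(pe0$SBP, rep(0, 3))
  # single-value check: 110 vs 100 -> 10%
  expect_equal(100 * abs(110 - 100) / 100, 10)
})

test_that("Bland-Altman statistics match hand-computed values", {
  est <- mk_bp(c(121, 119, 122))
  ref <- mk_bp(c(120, 120, 120))
  rep1 <- bland_altman_pearson(pair_series(est, ref))
  row <- rep1$table[rep1$table$param == "SBP", ]
  expect_equal(row$mean_bias, 2 / 3, tolerance = 1e-9)
  expect_equal(row$sd_diff, stats::sd(c(1, -1, 2)), tolerance = 1e-9)
  expect_equal(row$sd_diff, 1.5275252, tolerance = 1e-6)
  expect_equal(row$loa_95_hi, 2 / 3 + 1.96 * row$sd_diff, tolerance = 1e-12)
  expect_equal(row$loa_68_lo, 2 / 3 - row$sd_diff, tolerance = 1e-12)
  # a zero-variance reference makes r not evaluable
  expect_true(is.na(row$pearson_r))

  idm <- bland_altman_pearson(pair_series(est, est))
  irow <- idm$table[idm$table$param == "SBP", ]
  expect_equal(irow$mean_bias, 0)
  expect_equal(irow$sd_diff, 0)
  expect_true(irow$aami_pass)

  off <- est
  off$SBP <- est$SBP + 6
  orow <- bland_altman_pearson(pair_series(off, est))$table
  orow <- orow[orow$param == "SBP", ]
  expect_equal(orow$mean_bias, 6)
  expect_false(orow$aami_pass) # |bias| 6 > 5 mmHg
})

test_that("agreement is antisymmetric and r is affine-invariant", {
  set.seed(62)
  a <- mk_bp(110 + stats::rnorm(40, 0, 4))
  b <- mk_bp(110 + stats::rnorm(40, 0, 4))
  ab <- bland_altman_pearson(pair_series(a, b))$table
  ba <- bland_altman_pearson(pair_series(b, a))$table
  expect_equal(ab$mean_bias, -ba$mean_bias, tolerance = 1e-12)
  expect_equal(ab$sd_diff, ba$sd_diff, tolerance = 1e-12)
  expect_equal(ab$pearson_r, ba$pearson_r, tolerance = 1e-12)

  a2 <- a
  a2$SBP <- 2.5 * a$SBP + 7
  r1 <- bland_altman_pearson(pair_series(a, b))$table
  r2 <- bland_altman_pearson(pair_series(a2, b))$table
  expect_equal(r1$pearson_r[r1$param == "SBP"],
               r2$pearson_r[r2$param == "SBP"], tolerance = 1e-12)
})

test_that("the AAMI verdict is monotone in bias and spread", {
  base <- mk_bp(rep(100, 20) + rep(c(-1, 1), 10))
  ref <- mk_bp(rep(100, 20))
  verdict <- function(bias, noise_k) {
    est <- ref
    est$SBP <- ref$SBP + bias + noise_k * rep(c(-1, 1), 10)
    tab <- bland_altman_pearson(pair_series(est, ref))$table
    tab$aami_pass[tab$param == "SBP"]
  }
  expect_true(verdict(0, 1))
  expect_true(verdict(4.9, 1))
  expect_false(verdict(5.1, 1))
  expect_false(verdict(5.1, 9)) # growing spread never flips fail -> pass
  expect_false(verdict(0, 9))
})

test_that("the Brown-Forsythe test separates unequal variability", {
  set.seed(63)
  same <- stats::rnorm(20, 2, 0.3)
  expect_false(bpv_equivalence_test(same, same)$different)

  # window SDs near 1.0 versus near 5.0 mmHg, proportional jitter: the
  # absolute deviations scale with the level, so the test separates them
  a <- 1 * (1 + stats::rnorm(20, 0, 0.02))
  b <- 5 * (1 + stats::rnorm(20, 0, 0.02))
  expect_true(bpv_equivalence_test(a, b)$different)

  # degenerate all-equal input
  expect_equal(bpv_equivalence_test(rep(1, 5), rep(1, 5))$p_value, 1)
})

test_that("Brown-Forsythe type-I error is near nominal and matches car", {
  set.seed(64)
  n_rep <- 500
  rej <- vapply(seq_len(n_rep), function(i) {
    a <- stats::rnorm(15, 10, 2)
    b <- stats::rnorm(15, 10, 2)
    bpv_equivalence_test(a, b)$p_value < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_gte(mean(rej), 0.05 - 2.5 * se)
  expect_lte(mean(rej), 0.05 + 2.5 * se)

  # cross-check the p-value against the reference implementation
  a <- stats::rnorm(25, 1, 0.5)
  b <- stats::rnorm(25, 1, 1.5)
  ours <- bpv_equivalence_test(a, b)$p_value
  lev <- car::leveneTest(c(a, b), factor(rep(c("a", "b"), each = 25)),
                         center = stats::median)
  expect_equal(ours, lev[["Pr(>F)"]][1], tolerance = 1e-9)
})
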