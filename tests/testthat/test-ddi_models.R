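test_that("reporting odds ratio matches its closed form and criteria", {
  # identity table
  r <- reporting_odds_ratio(list(a = 1, b = 1, c = 1, d = 1))
  expect_equal(r$ror, 1)
  expect_false(r$flag)

  # strong signal, hand-computed closed form
  r <- reporting_odds_ratio(list(a = 20, b = 80, c = 100, d = 9800))
  expect_equal(r$ror, 24.5)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 100 + 1 / 9800)
  expect_equal(r$ci_low, exp(log(24.5) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(log(24.5) + 1.96 * se), tolerance = 1e-12)
  expect_equal(round(r$ci_low, 2), 14.45)
  expect_equal(round(r$ci_high, 2), 41.55)
  expect_true(r$flag)

  # zero cell: continuity correction on all four cells; too few cases
  r <- reporting_odds_ratio(list(a = 0, b = 10, c = 5, d = 985))
  expect_true(r$corrected)
  expect_equal(r$ror, (0.5 * 985.5) / (10.5 * 5.5))
  expect_false(r$flag)  # n_cases < 3

  # all-zero table is not evaluable, never a crash
  r <- reporting_odds_ratio(list(a = 0, b = 0, c = 0, d = 0))
  expect_false(r$evaluable)
  expect_true(is.na(r$flag))
})

test_that("the no-interaction baseline reproduces the null case and variants", {
  # equal stratum risks: expected proportion equals the background
  x <- pc(5, 995, 5, 995, 5, 995, 5, 995)
  for (v in c("noren", "reciprocal", "max")) {
    bl <- no_interaction_baseline(x, variant = v)
    expect_true(bl$evaluable)
    expect_equal(bl$g11_expected, bl$g00, tolerance = 1e-12)
    expect_equal(bl$e111, bl$g00 * x$n11p, tolerance = 1e-12)
    expect_false(bl$fallback_used)
  }
  # any empty stratum disables the baseline
  bl <- no_interaction_baseline(pc(0, 0, 1, 9, 1, 9, 5, 985))
  expect_false(bl$evaluable)
})

test_that("reciprocal-variant arithmetic matches the worked example and falls back on sign", {
  # unshrunk arithmetic of the combination rule itself:
  # 1/g11 = 1/0.010 + 1/0.008 - 1/0.005 = 100 + 125 - 200 = 25
  cmb <- tdpddi:::combine_g11(0.005, 0.010, 0.008, "reciprocal")
  expect_equal(cmb$g11, 0.04, tolerance = 1e-12)
  expect_false(cmb$fallback_used)
  # e111 on the stated strata (n11+ = 500)
  expect_equal(cmb$g11 * 500, 20)
  # negative reciprocal sum (33.3 + 50 - 100 < 0) falls back to max
  cmb <- tdpddi:::combine_g11(0.01, 0.03, 0.02, "reciprocal")
  expect_true(cmb$fallback_used)
  expect_equal(cmb$g11, 0.03)
})

test_that("the default baseline is risk-additive for rare events", {
  # g10 = g01 = 3 g00 with g00 small: expectation ~ g10 + g01 - g00
  x <- pc(0, 500, 15, 985, 15, 985, 50, 9950)
  bl <- no_interaction_baseline(x, variant = "noren")
  g00 <- (50 + 0.5) / (10000 + 0.5)
  g10 <- (15 + 0.5) / (1000 + 0.5)
  additive <- g10 + g10 - g00
  expect_false(bl$fallback_used)
  expect_equal(bl$g11_expected, additive, tolerance = 0.05)
  # and it never exceeds the reciprocal-complement closed form exactly
  h <- 1 / (1 - g10) + 1 / (1 - g10) - 1 / (1 - g00)
  expect_equal(bl$g11_expected, 1 - 1 / h, tolerance = 1e-12)
})

test_that("omega measure matches hand computation and flags per criteria", {
  # observed equals expected
  om <- omega_measure(20, 20)
  expect_equal(om$omega, 0)
  expect_lt(om$omega025, 0)

  # n111 = 40, e111 = 20
  om <- omega_measure(40, 20)
  expect_equal(om$omega, log2(40.5 / 20.5), tolerance = 1e-12)
  expect_equal(om$omega025, log2(40.5 / 20.5) - 3.3 / sqrt(40) - 2 / 40^0.75,
               tolerance = 1e-12)
  expect_equal(round(om$omega, 3), 0.982)
  expect_equal(round(om$omega025, 3), 0.335)

  # n111 = 3, e111 = 0: sparse-data flag just above zero
  om <- omega_measure(3, 0)
  expect_equal(om$omega, log2(3.5 / 0.5), tolerance = 1e-12)
  expect_equal(om$omega025, log2(7) - 3.3 / sqrt(3) - 2 / 3^0.75,
               tolerance = 1e-12)
  expect_gt(om$omega025, 0)
  expect_lt(om$omega025, 0.03)
})

test_that("omega on a pair table uses the shared baseline and min-case rule", {
  # construct counts whose noren baseline gives e111 far below n111
  x <- pc(40, 460, 20, 1980, 16, 1984, 50, 9950)
  r <- omega_shrinkage(x)
  expect_true(r$evaluable)
  ora <- o_baseline(x, "noren")
  expect_equal(r$e111, ora$e111, tolerance = 1e-12)
  expect_equal(r$omega, unname(o_omega(40, ora$e111)["omega"]),
               tolerance = 1e-12)
  expect_true(r$flag)
  # same statistics but n111 below the min-case rule cannot flag
  x2 <- pc(2, 23, 1, 99, 1, 99, 5, 995)
  r2 <- omega_shrinkage(x2)
  expect_false(isTRUE(r2$flag))
})

test_that("signed Yates chi-square matches hand computation", {
  # n11+ = 500, n111 = 40 against e111 = 20 (use a baseline-free check
  # through the internal formula: term 19.5, chi2 = 19.5^2 (1/20 + 1/480))
  x <- pc(40, 460, 20, 1980, 16, 1984, 50, 9950)
  bl <- no_interaction_baseline(x)
  r <- chi_square_yates(x, baseline = list(e111 = 20, evaluable = TRUE))
  expect_equal(r$chi, sqrt(19.5^2 * (1 / 20 + 1 / 480)), tolerance = 1e-12)
  expect_equal(round(r$chi, 2), 4.45)
  expect_true(r$flag)

  # observed equals expected: zero by the continuity term
  r0 <- chi_square_yates(x, baseline = list(e111 = 40, evaluable = TRUE))
  expect_equal(r0$chi, 0)
  expect_false(r0$flag)
  # |n111 - e111| <= 0.5 also collapses to zero
  r05 <- chi_square_yates(x, baseline = list(e111 = 40.4, evaluable = TRUE))
  expect_equal(r05$chi, 0)

  # deficits give negative chi and never flag
  rneg <- chi_square_yates(x, baseline = list(e111 = 400, evaluable = TRUE))
  expect_lt(rneg$chi, -2)
  expect_false(rneg$flag)

  # degenerate expectations are not evaluable
  rdeg <- chi_square_yates(x, baseline = list(e111 = 0, evaluable = TRUE))
  expect_true(is.na(rdeg$flag))
})

test_that("combination risk ratio matches the worked example", {
  x <- pc(40, 460, 20, 1980, 16, 1984, 50, 9950)
  r <- combination_risk_ratio(x)
  expect_equal(r$prr_combo, (40 / 500) / (50 / 10000), tolerance = 1e-12)
  expect_equal(r$prr_combo, 16)
  expect_equal(r$prr10, 2)
  expect_equal(r$prr01, 1.6)
  expect_equal(r$crr, 8)
  expect_equal(r$chi2_combo, o_yates2x2(40, 460, 50, 9950), tolerance = 1e-12)
  expect_equal(round(r$chi2_combo, 1), 306.4)
  expect_true(r$flag)
})

test_that("combination risk ratio guards its reference stratum and denominator", {
  # equal stratum risks: all ratios 1, no flag
  x <- pc(5, 995, 5, 995, 5, 995, 5, 995)
  r <- combination_risk_ratio(x)
  expect_equal(c(r$prr_combo, r$prr10, r$prr01, r$crr), rep(1, 4))
  expect_false(r$flag)

  # a strong single-drug signal suppresses the pair despite a high PRR_combo
  # (prr10 = 12, prr_combo = 13 -> crr ~ 1.08)
  x <- pc(13, 87, 120, 880, 10, 990, 100, 9900)
  r <- combination_risk_ratio(x)
  expect_equal(r$prr10, 12)
  expect_equal(r$prr_combo, 13)
  expect_equal(r$crr, 13 / 12, tolerance = 1e-12)
  expect_false(r$flag)

  # zero reference events: +0.5 continuity on the defining cells
  x <- pc(4, 96, 2, 98, 2, 98, 0, 1000)
  r <- combination_risk_ratio(x)
  want <- o_crr(x)
  expect_equal(r$prr_combo, want$prr_combo, tolerance = 1e-12)
  expect_equal(r$crr, want$crr, tolerance = 1e-12)

  # an empty stratum is not evaluable
  x <- pc(3, 0, 0, 0, 2, 98, 5, 995)
  expect_true(is.na(combination_risk_ratio(x)$flag))
})

test_that("additive contrast matches arithmetic and flags multiplicative pairs", {
  # exact additivity boundary
  x <- pc(5, 995, 5, 995, 5, 995, 5, 995)
  r <- additive_contrast(x)
  expect_equal(r$contrast, 0)
  expect_false(r$flag)

  # p11=0.08, p10=0.01, p01=0.008, p00=0.005 -> contrast 0.067
  x <- pc(40, 460, 10, 990, 8, 992, 5, 995)
  r <- additive_contrast(x)
  expect_equal(r$contrast, 0.08 - 0.01 - 0.008 + 0.005, tolerance = 1e-12)
  expect_true(r$flag)

  # purely multiplicative risks still exceed the additive prediction
  # (p00=0.01, p10=0.02, p01=0.03, p11=0.06 -> contrast 0.02): the model's
  # documented over-detection
  x <- pc(60, 940, 20, 980, 30, 970, 10, 990)
  r <- additive_contrast(x)
  expect_equal(r$contrast, 0.02, tolerance = 1e-12)
  expect_true(r$flag)

  # empty stratum: not evaluable
  x <- pc(3, 0, 0, 0, 2, 98, 5, 995)
  expect_true(is.na(additive_contrast(x)$flag))
})

test_that("every pair statistic is invariant under drug swap", {
  set.seed(101)
  for (rep in 1:25) {
    cells <- as.list(rmultinom(1, size = 2000,
                               prob = c(0.002, 0.02, 0.005, 0.1,
                                        0.004, 0.1, 0.01, 0.759))[, 1])
    names(cells) <- c("n111", "n110", "n101", "n100",
                      "n011", "n010", "n001", "n000")
    x <- do.call(pc, cells)
    y <- pc_swapped(x)
    for (v in c("noren", "reciprocal", "max")) {
      bx <- no_interaction_baseline(x, v); by <- no_interaction_baseline(y, v)
      expect_equal(bx$e111, by$e111, tolerance = 1e-12)
      ox <- omega_shrinkage(x, v); oy <- omega_shrinkage(y, v)
      expect_identical(ox$flag, oy$flag)
      cx <- chi_square_yates(x, v); cy <- chi_square_yates(y, v)
      expect_equal(cx$chi, cy$chi, tolerance = 1e-12)
    }
    rx <- combination_risk_ratio(x); ry <- combination_risk_ratio(y)
    expect_equal(rx$crr, ry$crr, tolerance = 1e-12)
    expect_equal(rx$chi2_combo, ry$chi2_combo, tolerance = 1e-12)
    ax <- additive_contrast(x); ay <- additive_contrast(y)
    expect_equal(ax$contrast, ay$contrast, tolerance = 1e-12)
  }
})

test_that("shrinkage is conservative and omega monotone in n111", {
  # omega < log2(n111/e111) whenever n111 > e111
  for (n111 in c(5, 20, 80)) {
    for (e111 in c(1, 4, 15)) {
      if (n111 > e111) {
        expect_lt(omega_measure(n111, e111)$omega, log2(n111 / e111))
      }
    }
  }
  # nondecreasing in n111 at fixed e111; omega025 always below omega
  oms <- vapply(1:50, function(n) omega_measure(n, 10)$omega, 1)
  expect_true(all(diff(oms) > 0))
  o25 <- vapply(1:50, function(n) omega_measure(n, 10)$omega025, 1)
  expect_true(all(diff(o25) > 0))
  expect_true(all(o25 < oms))
})

test_that("run_all_models rows agree with the scalar models and consensus is the intersection", {
  coll <- random_collection(n_reports = 400, n_drugs = 8, seed = 31,
                            event_prob = 0.3)
  flags <- mark_cases(coll, TARGET_PT)
  pairs <- eligible_pairs(coll, flags, min_cases = 1, min_drug_cases = 1)
  sig <- run_all_models(pairs, min_cases = 1)
  expect_gt(nrow(sig), 0)
  for (i in seq_len(nrow(sig))) {
    ct <- pair_counts_row(pairs, i)
    expect_equal(sig$omega025[i], omega_shrinkage(ct, min_cases = 1)$omega025)
    expect_equal(sig$crr[i], combination_risk_ratio(ct, min_cases = 1)$crr)
  }
  expect_equal(sig$consensus,
               sig$omega_flag %in% TRUE & sig$chi_flag %in% TRUE &
                 sig$crr_flag %in% TRUE & sig$additive_flag %in% TRUE)
  # containment: consensus set within each model's flag set
  expect_true(all(!sig$consensus | sig$omega_flag %in% TRUE))
  # a pair not evaluable under any model cannot be consensus
  expect_true(all(!(is.na(sig$additive_flag) & sig$consensus)))
})
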