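#' Single-drug reporting odds ratio
#'
#' `ROR = (a x d) / (b x c)` from the single-drug 2x2 table, with a
#' Haldane-Anscombe correction (+0.5 on all four cells) whenever any cell
#' is zero, and the log-scale 95% CI
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. The positivity
#' criterion is `ROR > 2` and CI lower bound `> 1` with at least
#' `min_cases` case reports of the drug.
#'
#' @param counts a [single_drug_counts()] object, or a list with elements
#'   `a`, `b`, `c`, `d`.
#' @param min_cases minimum `a` cell for a positive signal (default 3).
#' @return a list of class `ror_result` with `ror`, `ci_low`, `ci_high`,
#'   `n_cases`, `corrected` (logical: continuity correction applied),
#'   `evaluable` and `flag` (`NA` when not evaluable).
#' @export
reporting_odds_ratio <- function(counts, min_cases = 3) {
  a <- counts$a; b <- counts$b; cc <- counts$c; d <- counts$d
  if (any(c(a, b, cc, d) < 0)) stop("cells must be nonnegative", call. = FALSE)
  n <- a + b + cc + d
  if (n == 0) {
    return(structure(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          n_cases = 0L, corrected = FALSE, evaluable = FALSE,
                          flag = NA),
                     class = "ror_result"))
  }
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) { a2 <- a + 0.5; b2 <- b + 0.5; c2 <- cc + 0.5; d2 <- d + 0.5 }
  else { a2 <- a; b2 <- b; c2 <- cc; d2 <- d }
  ror <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  ci_low <- exp(log(ror) - 1.96 * se)
  ci_high <- exp(log(ror) + 1.96 * se)
  structure(list(
    ror = ror, ci_low = ci_low, ci_high = ci_high, n_cases = a,
    corrected = corrected, evaluable = TRUE,
    flag = (ror > 2 && ci_low > 1 && a >= min_cases)
  ), class = "ror_result")
}

# combine stratum event proportions into the no-interaction expectation.
# variants:
#   noren      - additive on h(f) = 1/(1-f) (the published interaction
#                surveillance baseline; ~ risk-additive for rare events)
#   reciprocal - additive on 1/f (reciprocal event proportions)
#   max        - the larger single-drug stratum proportion
# fallback to max(g10, g01) when the combination rule is undefined or
# non-positive; result capped at 1.
combine_g11 <- function(g00, g10, g01, variant = c("noren", "reciprocal", "max")) {
  variant <- match.arg(variant)
  fallback <- FALSE
  if (variant == "noren") {
    h <- 1 / (1 - g10) + 1 / (1 - g01) - 1 / (1 - g00)
    if (h > 1) {
      g11 <- 1 - 1 / h
    } else {
      g11 <- max(g10, g01)
      fallback <- TRUE
    }
  } else if (variant == "reciprocal") {
    r <- 1 / g10 + 1 / g01 - 1 / g00
    if (r > 0) {
      g11 <- 1 / r
    } else {
      g11 <- max(g10, g01)
      fallback <- TRUE
    }
  } else {
    g11 <- max(g10, g01)
  }
  list(g11 = min(g11, 1), fallback_used = fallback)
}

#' No-interaction baseline for a drug pair
#'
#' Computes shrunk stratum event proportions
#' `g_ij = (n_ij1 + 0.5) / (n_ij+ + 0.5)` and combines the single-drug and
#' background strata into the expected co-exposed proportion `g11` under no
#' interaction, giving the expected co-exposed case count
#' `e111 = g11 * n11+`. The default `"noren"` variant is additive on
#' `1/(1 - g)` (for rare events essentially the risk-additive baseline
#' `g10 + g01 - g00`); `"reciprocal"` is additive on `1/g`; `"max"` takes
#' the larger single-drug proportion. When a combination rule is undefined
#' or non-positive the baseline falls back to `max(g10, g01)` and
#' `fallback_used` is set.
#'
#' @param counts a [pair_counts()] object (or list with the eight cells).
#' @param variant baseline combination rule, see Details.
#' @return list of class `ddi_baseline`: `g00`, `g10`, `g01`,
#'   `g11_expected`, `e111`, `fallback_used`, `evaluable` (`FALSE` when any
#'   stratum total is zero).
#' @export
no_interaction_baseline <- function(counts,
                                    variant = c("noren", "reciprocal", "max")) {
  variant <- match.arg(variant)
  counts <- ensure_margins(counts)
  if (min(counts$n11p, counts$n10p, counts$n01p, counts$n00p) == 0) {
    return(structure(list(g00 = NA_real_, g10 = NA_real_, g01 = NA_real_,
                          g11_expected = NA_real_, e111 = NA_real_,
                          fallback_used = FALSE, evaluable = FALSE,
                          variant = variant),
                     class = "ddi_baseline"))
  }
  g00 <- (counts$n001 + 0.5) / (counts$n00p + 0.5)
  g10 <- (counts$n101 + 0.5) / (counts$n10p + 0.5)
  g01 <- (counts$n011 + 0.5) / (counts$n01p + 0.5)
  cmb <- combine_g11(g00, g10, g01, variant)
  structure(list(
    g00 = g00, g10 = g10, g01 = g01,
    g11_expected = cmb$g11, e111 = cmb$g11 * counts$n11p,
    fallback_used = cmb$fallback_used, evaluable = TRUE, variant = variant
  ), class = "ddi_baseline")
}

ensure_margins <- function(counts) {
  if (is.null(counts$n11p)) {
    counts$n11p <- counts$n111 + counts$n110
    counts$n10p <- counts$n101 + counts$n100
    counts$n01p <- counts$n011 + counts$n010
    counts$n00p <- counts$n001 + counts$n000
  }
  counts
}

#' Omega shrinkage measure from observed and expected counts
#'
#' `Omega = log2((n111 + 0.5) / (e111 + 0.5))` with the lower 2.5%
#' credibility bound `Omega025 = Omega - 3.3 * n111^(-1/2) - 2 * n111^(-3/4)`.
#' The +0.5 shrinkage pulls extreme ratios toward zero; the bound is the
#' standard closed-form approximation used with this family of
#' observed-to-expected measures.
#'
#' @param n111 observed co-exposed case count.
#' @param e111 expected co-exposed case count under no interaction.
#' @return list with `omega` and `omega025` (`omega025` is `-Inf` at
#'   `n111 = 0`).
#' @export
omega_measure <- function(n111, e111) {
  omega <- log2((n111 + 0.5) / (e111 + 0.5))
  omega025 <- ifelse(n111 > 0,
                     omega - 3.3 * n111^(-0.5) - 2 * n111^(-0.75),
                     -Inf)
  list(omega = omega, omega025 = omega025)
}

#' Omega shrinkage measure model for a drug pair
#'
#' Shrunk log2 observed-to-expected ratio of co-exposed case counts against
#' the no-interaction baseline of [no_interaction_baseline()]. Positive
#' signal when `Omega025 > 0` and `n111 >= min_cases`.
#'
#' @inheritParams no_interaction_baseline
#' @param min_cases minimum co-exposed case count for a signal (default 3).
#' @param baseline optionally, a precomputed [no_interaction_baseline()].
#' @return list of class `omega_result` with the baseline components,
#'   `omega`, `omega025`, `evaluable` and `flag` (`NA` when not evaluable).
#' @export
omega_shrinkage <- function(counts, variant = c("noren", "reciprocal", "max"),
                            min_cases = 3, baseline = NULL) {
  counts <- ensure_margins(counts)
  if (is.null(baseline)) baseline <- no_interaction_baseline(counts, variant)
  if (!baseline$evaluable) {
    return(structure(c(unclass(baseline),
                       list(n111 = counts$n111, omega = NA_real_,
                            omega025 = NA_real_, flag = NA)),
                     class = "omega_result"))
  }
  om <- omega_measure(counts$n111, baseline$e111)
  structure(c(unclass(baseline),
              list(n111 = counts$n111, omega = om$omega,
                   omega025 = om$omega025,
                   flag = (om$omega025 > 0 && counts$n111 >= min_cases))),
            class = "omega_result")
}

#' Signed Yates-corrected chi-square model for a drug pair
#'
#' One-sample chi-square of the co-exposed event split `(n111, n110)`
#' against the no-interaction expectation `(e111, n11+ - e111)` shared with
#' the Omega model, with Yates continuity term
#' `max(|n111 - e111| - 0.5, 0)`:
#' `chi^2 = term^2 * (1/e111 + 1/e110)`, reported as the signed square root
#' `chi = sign(n111 - e111) * sqrt(chi^2)` so the criterion `chi > 2` is
#' one-sided for excess risk. Requires `0 < e111 < n11+`.
#'
#' @inheritParams omega_shrinkage
#' @return list of class `chi_result` with `chi`, `e111`, `evaluable` and
#'   `flag` (`NA` when not evaluable).
#' @export
chi_square_yates <- function(counts, variant = c("noren", "reciprocal", "max"),
                             min_cases = 3, baseline = NULL) {
  counts <- ensure_margins(counts)
  if (is.null(baseline)) baseline <- no_interaction_baseline(counts, variant)
  e111 <- baseline$e111
  if (!baseline$evaluable || is.na(e111) || e111 <= 0 || e111 >= counts$n11p) {
    return(structure(list(chi = NA_real_, e111 = e111, n111 = counts$n111,
                          evaluable = FALSE, flag = NA),
                     class = "chi_result"))
  }
  e110 <- counts$n11p - e111
  term <- max(abs(counts$n111 - e111) - 0.5, 0)
  chi2 <- term^2 * (1 / e111 + 1 / e110)
  chi <- sign(counts$n111 - e111) * sqrt(chi2)
  structure(list(chi = chi, e111 = e111, n111 = counts$n111, evaluable = TRUE,
                 flag = (chi > 2 && counts$n111 >= min_cases)),
            class = "chi_result")
}

yates_chi2_2x2 <- function(a, b, cc, d) {
  a <- as.numeric(a); b <- as.numeric(b); cc <- as.numeric(cc)
  d <- as.numeric(d)
  n <- a + b + cc + d
  num <- n * max(abs(a * d - b * cc) - n / 2, 0)^2
  den <- (a + b) * (cc + d) * (a + cc) * (b + d)
  if (den == 0) return(NA_real_)
  num / den
}

#' Combination risk ratio model for a drug pair
#'
#' Proportional reporting ratios against the neither-drug reference
#' stratum: `PRR_combo = (n111/n11+) / (n001/n00+)`, `PRR10` and `PRR01`
#' analogously for the single-drug strata, and the combination risk ratio
#' `CRR = PRR_combo / max(PRR10, PRR01)`. `chi2_combo` is the Yates
#' chi-square of the 2x2 table `[[n111, n110], [n001, n000]]`. When the
#' reference stratum has zero events (`n001 = 0`) a +0.5 continuity
#' correction is applied to the numerator and denominator cells of each
#' ratio. Positive signal when `PRR_combo > 2`, `chi2_combo > 4`,
#' `CRR > 2` and `n111 >= min_cases`.
#'
#' @inheritParams omega_shrinkage
#' @return list of class `crr_result` with `prr_combo`, `prr10`, `prr01`,
#'   `chi2_combo`, `crr`, `evaluable` and `flag` (`NA` when not evaluable).
#' @export
combination_risk_ratio <- function(counts, min_cases = 3) {
  counts <- ensure_margins(counts)
  not_eval <- structure(list(prr_combo = NA_real_, prr10 = NA_real_,
                             prr01 = NA_real_, chi2_combo = NA_real_,
                             crr = NA_real_, n111 = counts$n111,
                             evaluable = FALSE, flag = NA),
                        class = "crr_result")
  if (counts$n00p == 0 || counts$n11p == 0 || counts$n10p == 0 ||
      counts$n01p == 0) {
    return(not_eval)
  }
  correct <- counts$n001 == 0
  k <- if (correct) 0.5 else 0
  ref <- (counts$n001 + k) / (counts$n00p + k)
  prr_combo <- ((counts$n111 + k) / (counts$n11p + k)) / ref
  prr10 <- ((counts$n101 + k) / (counts$n10p + k)) / ref
  prr01 <- ((counts$n011 + k) / (counts$n01p + k)) / ref
  denom <- max(prr10, prr01)
  if (!is.finite(denom) || denom <= 0) return(not_eval)
  crr <- prr_combo / denom
  chi2_combo <- yates_chi2_2x2(counts$n111, counts$n110, counts$n001, counts$n000)
  structure(list(
    prr_combo = prr_combo, prr10 = prr10, prr01 = prr01,
    chi2_combo = chi2_combo, crr = crr, n111 = counts$n111, evaluable = TRUE,
    flag = (prr_combo > 2 && !is.na(chi2_combo) && chi2_combo > 4 &&
              crr > 2 && counts$n111 >= min_cases)
  ), class = "crr_result")
}

#' Additive risk-contrast model for a drug pair
#'
#' Observed (unshrunk) stratum event proportions `p_ij = n_ij1 / n_ij+`
#' and the interaction contrast `p11 - p10 - p01 + p00`. Positive signal
#' when the contrast exceeds 0 and `n111 >= min_cases`; the criterion is a
#' point-estimate comparison with no variance term, which is why this
#' model over-detects (purely multiplicative joint risks already exceed
#' the additive prediction).
#'
#' @inheritParams omega_shrinkage
#' @return list of class `additive_result` with `p11`, `p10`, `p01`,
#'   `p00`, `contrast`, `evaluable` and `flag` (`NA` when not evaluable).
#' @export
additive_contrast <- function(counts, min_cases = 3) {
  counts <- ensure_margins(counts)
  if (min(counts$n11p, counts$n10p, counts$n01p, counts$n00p) == 0) {
    return(structure(list(p11 = NA_real_, p10 = NA_real_, p01 = NA_real_,
                          p00 = NA_real_, contrast = NA_real_,
                          n111 = counts$n111, evaluable = FALSE, flag = NA),
                     class = "additive_result"))
  }
  p11 <- counts$n111 / counts$n11p
  p10 <- counts$n101 / counts$n10p
  p01 <- counts$n011 / counts$n01p
  p00 <- counts$n001 / counts$n00p
  contrast <- p11 - p10 - p01 + p00
  structure(list(p11 = p11, p10 = p10, p01 = p01, p00 = p00,
                 contrast = contrast, n111 = counts$n111, evaluable = TRUE,
                 flag = (contrast > 0 && counts$n111 >= min_cases)),
            class = "additive_result")
}

#' Run all four DDI models over eligible pairs
#'
#' Applies the Omega shrinkage measure, the signed Yates chi-square, the
#' combination risk ratio and the additive contrast to every pair, with
#' the all-four consensus flag (`TRUE` only when each model is evaluable
#' and positive). Model flags are three-valued: `TRUE`, `FALSE`, or `NA`
#' when the model is not evaluable for the pair.
#'
#' @param pairs a `pair_counts_table` from [eligible_pairs()].
#' @param min_cases minimum `n111` shared by all positivity criteria
#'   (default 3).
#' @param variant Omega/chi baseline variant, see
#'   [no_interaction_baseline()].
#' @return a `data.table` of class `ddi_signals`, one row per pair in
#'   canonical order: pair key, `n111`, all statistics, the four flags and
#'   `consensus`.
#' @export
run_all_models <- function(pairs, min_cases = 3,
                           variant = c("noren", "reciprocal", "max")) {
  variant <- match.arg(variant)
  n <- nrow(pairs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ct <- pair_counts_row(pairs, i)
    bl <- no_interaction_baseline(ct, variant)
    om <- omega_shrinkage(ct, variant, min_cases, baseline = bl)
    ch <- chi_square_yates(ct, variant, min_cases, baseline = bl)
    cr <- combination_risk_ratio(ct, min_cases)
    ad <- additive_contrast(ct, min_cases)
    rows[[i]] <- data.table(
      drug_low = ct$drug_low, drug_high = ct$drug_high,
      n111 = ct$n111, n11p = ct$n11p,
      e111 = bl$e111, fallback_used = bl$fallback_used,
      omega = om$omega, omega025 = om$omega025, omega_flag = om$flag,
      chi = ch$chi, chi_flag = ch$flag,
      prr_combo = cr$prr_combo, chi2_combo = cr$chi2_combo, crr = cr$crr,
      crr_flag = cr$flag,
      contrast = ad$contrast, additive_flag = ad$flag,
      consensus = isTRUE(om$flag) && isTRUE(ch$flag) && isTRUE(cr$flag) &&
        isTRUE(ad$flag)
    )
  }
  out <- if (n > 0) rbindlist(rows) else data.table(
    drug_low = character(), drug_high = character(), n111 = integer(),
    n11p = integer(), e111 = numeric(), fallback_used = logical(),
    omega = numeric(), omega025 = numeric(), omega_flag = logical(),
    chi = numeric(), chi_flag = logical(), prr_combo = numeric(),
    chi2_combo = numeric(), crr = numeric(), crr_flag = logical(),
    contrast = numeric(), additive_flag = logical(), consensus = logical()
  )
  setorder(out, drug_low, drug_high)
  structure(out, class = c("ddi_signals", class(out)))
}
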