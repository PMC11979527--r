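#' 2x2 concordance table of two flag vectors
#'
#' Tallies two models' signal flags over the shared pair universe:
#' `a` both positive, `b` first only, `c` second only, `d` both negative.
#' Pairs where either flag is `NA` (model not evaluable) are excluded
#' pairwise (complete-case per model pair); the exclusion count is
#' reported.
#'
#' @param flags_first,flags_second aligned logical vectors (same pair
#'   universe, same order).
#' @return list of class `agreement_table`: `a`, `b`, `c`, `d`, `n`
#'   (pairs rated by both) and `n_excluded`.
#' @export
agreement_table <- function(flags_first, flags_second) {
  if (length(flags_first) != length(flags_second)) {
    stop("flag vectors must be aligned (equal length)", call. = FALSE)
  }
  keep <- !is.na(flags_first) & !is.na(flags_second)
  f1 <- flags_first[keep]
  f2 <- flags_second[keep]
  structure(list(
    a = sum(f1 & f2), b = sum(f1 & !f2), c = sum(!f1 & f2), d = sum(!f1 & !f2),
    n = sum(keep), n_excluded = sum(!keep)
  ), class = "agreement_table")
}

#' Agreement statistics for a concordance table
#'
#' With `n = a + b + c + d`: observed agreement `po = (a + d)/n`, chance
#' agreement `pe = ((a+b)(a+c) + (c+d)(b+d))/n^2`, Cohen
#' `kappa = (po - pe)/(1 - pe)` with the large-sample 95% CI
#' `kappa +/- 1.96 * sqrt(po(1-po)/(n(1-pe)^2))`, and the proportionate
#' agreements `P_positive = 2a/(2a+b+c)`, `P_negative = 2d/(2d+b+c)`.
#' Degenerate constant raters (`pe = 1`) yield `kappa = NA`.
#'
#' @param table an [agreement_table()], or list with `a`, `b`, `c`, `d`.
#' @return list of class `agreement_result`: `po`, `pe`, `kappa`,
#'   `kappa_low`, `kappa_high`, `p_positive`, `p_negative`, `n`,
#'   `interpretation` (band label for the kappa point estimate).
#' @export
agreement_stats <- function(table) {
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  n <- a + b + cc + d
  if (n == 0) stop("agreement table is empty", call. = FALSE)
  po <- (a + d) / n
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  p_positive <- if (2 * a + b + cc > 0) 2 * a / (2 * a + b + cc) else NA_real_
  p_negative <- if (2 * d + b + cc > 0) 2 * d / (2 * d + b + cc) else NA_real_
  if (pe >= 1) {
    kappa <- kappa_low <- kappa_high <- NA_real_
  } else {
    kappa <- (po - pe) / (1 - pe)
    se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
    kappa_low <- kappa - 1.96 * se
    kappa_high <- kappa + 1.96 * se
  }
  structure(list(
    po = po, pe = pe, kappa = kappa, kappa_low = kappa_low,
    kappa_high = kappa_high, p_positive = p_positive,
    p_negative = p_negative, n = n,
    interpretation = kappa_interpretation(kappa)
  ), class = "agreement_result")
}

# agreement bands: slight / fair / moderate / substantial / excellent
kappa_interpretation <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa < 0) "less than chance"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "excellent"
}

MODEL_FLAG_COLUMNS <- c(
  omega = "omega_flag", chi = "chi_flag", crr = "crr_flag",
  additive = "additive_flag"
)

MODEL_LABELS <- c(
  omega = "omega shrinkage measure", chi = "chi-square statistic",
  crr = "combination risk ratio", additive = "additive"
)

#' Pairwise agreement of the four DDI models
#'
#' Computes [agreement_stats()] for all six model pairs over a
#' [run_all_models()] signal table, in the conventional order (omega vs
#' chi-square, omega vs combination risk ratio, omega vs additive,
#' chi-square vs combination risk ratio, chi-square vs additive,
#' combination risk ratio vs additive).
#'
#' @param signals a `ddi_signals` table from [run_all_models()].
#' @return a `data.table` with one row per model pair: the concordance
#'   cells, `p_positive`, `p_negative`, `kappa` with CI, `n_excluded` and
#'   the interpretation band.
#' @export
agreement_matrix <- function(signals) {
  if (nrow(signals) == 0) stop("signal table is empty", call. = FALSE)
  combos <- list(c("omega", "chi"), c("omega", "crr"), c("omega", "additive"),
                 c("chi", "crr"), c("chi", "additive"), c("crr", "additive"))
  rows <- lapply(combos, function(cm) {
    f1 <- signals[[MODEL_FLAG_COLUMNS[[cm[1]]]]]
    f2 <- signals[[MODEL_FLAG_COLUMNS[[cm[2]]]]]
    tab <- agreement_table(f1, f2)
    st <- agreement_stats(tab)
    data.table(
      model_first = MODEL_LABELS[[cm[1]]], model_second = MODEL_LABELS[[cm[2]]],
      a = tab$a, b = tab$b, c = tab$c, d = tab$d, n = tab$n,
      n_excluded = tab$n_excluded,
      p_positive = st$p_positive, p_negative = st$p_negative,
      kappa = st$kappa, kappa_low = st$kappa_low, kappa_high = st$kappa_high,
      interpretation = st$interpretation
    )
  })
  rbindlist(rows)
}
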