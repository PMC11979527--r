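#' Normalize drug names
#'
#' Trims surrounding whitespace, collapses internal whitespace runs and
#' case-folds to lower case. No trade-name to generic mapping is attempted;
#' supply a synonym table to [read_reports()] for that.
#'
#' @param x character vector of raw drug names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_drug_name(c("  AMIODARONE ", "Sotalol  HCl"))
normalize_drug_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Canonical unordered drug-pair key
#'
#' Orders the two (already normalized) drug names lexicographically so that
#' a pair has a single canonical representation; all pair statistics are
#' symmetric, so orientation never matters.
#'
#' @param drug1,drug2 character vectors of equal length.
#' @return a list with components `drug_low` and `drug_high`.
#' @export
pair_key <- function(drug1, drug2) {
  if (length(drug1) != length(drug2)) {
    stop("drug1 and drug2 must have the same length", call. = FALSE)
  }
  if (any(drug1 == drug2)) {
    stop("a drug pair must consist of two distinct drugs", call. = FALSE)
  }
  swap <- drug1 > drug2
  list(
    drug_low  = ifelse(swap, drug2, drug1),
    drug_high = ifelse(swap, drug1, drug2)
  )
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# round half up to `digits` decimals (Table-2 style display rounding);
# R's round() is round-half-even, which Table 2 does not use.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Percentage of a count, rounded half-up to one decimal
#'
#' @param count nonnegative integer count.
#' @param total positive integer total with `count <= total`.
#' @return `100 * count / total` rounded half-up to one decimal place.
#' @export
#' @examples
#' percentage(363, 4313)  # 8.4
percentage <- function(count, total) {
  if (length(total) == 1L) total <- rep(total, length(count))
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(count < 0) || any(count > total)) {
    stop("count must satisfy 0 <= count <= total", call. = FALSE)
  }
  round_half_up(100 * count / total, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
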