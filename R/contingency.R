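#' Single-drug 2x2 contingency table
#'
#' Cross-classifies the analyzable reports (those with at least one drug
#' entry) by exposure to `drug` and occurrence of the target event:
#' `a` drug & event, `b` drug & no event, `c` no drug & event, `d` neither.
#' Exposure uses the deduplicated per-report drug set, under any role code.
#'
#' @param collection a [report_collection()].
#' @param case_flags named logical vector from [mark_cases()].
#' @param drug normalized drug name.
#' @return a list of class `single_drug_counts` with elements `drug`, `a`,
#'   `b`, `c`, `d` and `N = a + b + c + d`.
#' @export
single_drug_counts <- function(collection, case_flags, drug) {
  drug <- normalize_drug_name(drug)
  if (length(drug) != 1L || is.na(drug) || drug == "") {
    stop("drug must be a single non-empty name", call. = FALSE)
  }
  ids <- analyzable_ids(collection)
  cases <- names(case_flags)[case_flags]
  expo <- exposure_table(collection)
  exposed <- unique(expo[drug_name == drug, report_id])
  is_case <- ids %in% cases
  is_exp <- ids %in% exposed
  out <- list(
    drug = drug,
    a = sum(is_exp & is_case),
    b = sum(is_exp & !is_case),
    c = sum(!is_exp & is_case),
    d = sum(!is_exp & !is_case)
  )
  out$N <- out$a + out$b + out$c + out$d
  structure(out, class = "single_drug_counts")
}

#' Drug-pair 4x2 contingency table
#'
#' Partitions the analyzable reports into the eight cells `n_ijk`, where
#' `i` indicates exposure to the first drug, `j` exposure to the second and
#' `k` event occurrence; stratum totals `n11p`, `n10p`, `n01p`, `n00p`
#' (`p` for the `+` margin) are attached. Swapping the two drugs permutes
#' the cells consistently, and every downstream statistic is invariant
#' under the swap.
#'
#' @inheritParams single_drug_counts
#' @param drug1,drug2 distinct normalized drug names.
#' @return a list of class `pair_counts` with the eight cells, margins and
#'   the canonical pair key.
#' @export
pair_counts <- function(collection, case_flags, drug1, drug2) {
  drug1 <- normalize_drug_name(drug1)
  drug2 <- normalize_drug_name(drug2)
  if (drug1 == drug2) stop("drug1 and drug2 must differ", call. = FALSE)
  ids <- analyzable_ids(collection)
  cases <- names(case_flags)[case_flags]
  expo <- exposure_table(collection)
  e1 <- ids %in% expo[drug_name == drug1, report_id]
  e2 <- ids %in% expo[drug_name == drug2, report_id]
  ev <- ids %in% cases
  key <- pair_key(drug1, drug2)
  cells_from_indicators(e1, e2, ev, key$drug_low, key$drug_high,
                        swap = key$drug_low != drug1)
}

cells_from_indicators <- function(e1, e2, ev, drug_low, drug_high, swap = FALSE) {
  if (swap) { tmp <- e1; e1 <- e2; e2 <- tmp }
  out <- list(
    drug_low = drug_low, drug_high = drug_high,
    n111 = sum(e1 & e2 & ev),   n110 = sum(e1 & e2 & !ev),
    n101 = sum(e1 & !e2 & ev),  n100 = sum(e1 & !e2 & !ev),
    n011 = sum(!e1 & e2 & ev),  n010 = sum(!e1 & e2 & !ev),
    n001 = sum(!e1 & !e2 & ev), n000 = sum(!e1 & !e2 & !ev)
  )
  new_pair_counts(out)
}

new_pair_counts <- function(x) {
  x$n11p <- x$n111 + x$n110
  x$n10p <- x$n101 + x$n100
  x$n01p <- x$n011 + x$n010
  x$n00p <- x$n001 + x$n000
  x$N <- x$n11p + x$n10p + x$n01p + x$n00p
  structure(x, class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("<pair_counts> ", x$drug_low, " + ", x$drug_high, " (N = ", x$N, ")\n",
      sep = "")
  m <- matrix(c(x$n111, x$n110, x$n101, x$n100, x$n011, x$n010, x$n001, x$n000),
              ncol = 2, byrow = TRUE,
              dimnames = list(c("both", "drug1 only", "drug2 only", "neither"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Enumerate eligible drug pairs
#'
#' Finds every unordered pair of distinct drugs co-reported in at least
#' `min_cases` target-event case reports (`n111 >= min_cases`), after a
#' drug-level screen keeping drugs that appear in at least
#' `min_drug_cases` case reports. Candidate pairs are generated only from
#' drugs co-occurring within case reports (sparse streaming over reports;
#' no dense drug-by-drug matrix), which is exhaustive because any pair with
#' `n111 >= 1` co-occurs in a case report.
#'
#' @inheritParams single_drug_counts
#' @param min_cases minimum co-exposed case count `n111` (default 3).
#' @param min_drug_cases drug-level screen: minimum number of case reports
#'   a drug must appear in before it can enter a pair (default 3).
#' @return a `data.table` of class `pair_counts_table`, one row per
#'   eligible pair (sorted by pair key) with the eight cells and margins.
#' @export
eligible_pairs <- function(collection, case_flags, min_cases = 3,
                           min_drug_cases = 3) {
  if (min_cases < 1) stop("min_cases must be >= 1", call. = FALSE)
  ids <- analyzable_ids(collection)
  cases <- names(case_flags)[case_flags]
  expo <- exposure_table(collection)
  n_analyzable <- length(ids)
  case_ids <- intersect(cases, ids)
  n_cases <- length(case_ids)

  empty <- data.table(
    drug_low = character(), drug_high = character(),
    n111 = integer(), n110 = integer(), n101 = integer(), n100 = integer(),
    n011 = integer(), n010 = integer(), n001 = integer(), n000 = integer(),
    n11p = integer(), n10p = integer(), n01p = integer(), n00p = integer(),
    N = integer()
  )
  if (n_cases == 0L || nrow(expo) == 0L) {
    return(structure(empty, class = c("pair_counts_table", class(empty))))
  }

  # drug-level screen on case reports
  case_expo <- expo[report_id %in% case_ids]
  drug_case_n <- case_expo[, list(n_case_reports = .N), by = drug_name]
  screened <- drug_case_n[n_case_reports >= min_drug_cases, drug_name]
  case_expo <- case_expo[drug_name %in% screened]
  if (nrow(case_expo) == 0L) {
    return(structure(empty, class = c("pair_counts_table", class(empty))))
  }

  # sparse candidate generation: pairs co-occurring within a case report
  pairs_by_report <- case_expo[, {
    d <- sort(drug_name)
    if (length(d) >= 2L) {
      cmb <- combn(d, 2L)
      list(drug_low = cmb[1L, ], drug_high = cmb[2L, ])
    } else {
      list(drug_low = character(), drug_high = character())
    }
  }, by = report_id]
  if (nrow(pairs_by_report) == 0L) {
    return(structure(empty, class = c("pair_counts_table", class(empty))))
  }
  cand <- pairs_by_report[, list(n111 = .N), by = list(drug_low, drug_high)]
  cand <- cand[n111 >= min_cases]
  setorder(cand, drug_low, drug_high)
  if (nrow(cand) == 0L) {
    return(structure(empty, class = c("pair_counts_table", class(empty))))
  }

  # full 4x2 cells from per-drug exposure sets (sparse; one pass per pair)
  drugs_needed <- unique(c(cand$drug_low, cand$drug_high))
  expo_needed <- expo[drug_name %in% drugs_needed]
  exp_sets <- split(expo_needed$report_id, expo_needed$drug_name)
  case_set <- case_ids
  exp_case_n <- vapply(exp_sets, function(s) length(intersect(s, case_set)), 0L)

  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    d1 <- cand$drug_low[i]; d2 <- cand$drug_high[i]
    s1 <- exp_sets[[d1]]; s2 <- exp_sets[[d2]]
    both <- intersect(s1, s2)
    n11p <- length(both)
    n111 <- length(intersect(both, case_set))
    a1 <- exp_case_n[[d1]]; a2 <- exp_case_n[[d2]]
    n101 <- a1 - n111
    n011 <- a2 - n111
    n001 <- n_cases - a1 - a2 + n111
    n10p <- length(s1) - n11p
    n01p <- length(s2) - n11p
    n00p <- n_analyzable - length(s1) - length(s2) + n11p
    rows[[i]] <- data.table(
      drug_low = d1, drug_high = d2,
      n111 = n111, n110 = n11p - n111,
      n101 = n101, n100 = n10p - n101,
      n011 = n011, n010 = n01p - n011,
      n001 = n001, n000 = n00p - n001,
      n11p = n11p, n10p = n10p, n01p = n01p, n00p = n00p,
      N = n_analyzable
    )
  }
  out <- rbindlist(rows)
  structure(out, class = c("pair_counts_table", class(out)))
}

#' Extract one pair's counts from an eligible-pairs table
#'
#' @param tab a `pair_counts_table` from [eligible_pairs()].
#' @param i row index.
#' @return a `pair_counts` object for that row.
#' @export
pair_counts_row <- function(tab, i) {
  r <- as.list(tab[i, ])
  new_pair_counts(r[c("drug_low", "drug_high", "n111", "n110", "n101", "n100",
                      "n011", "n010", "n001", "n000")])
}
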