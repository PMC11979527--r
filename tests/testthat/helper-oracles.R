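# Independent brute-force oracles: plain loops over reports and literal
# formula transcriptions, deliberately sharing no code with the package.

# per-report deduplicated drug sets, in report order
report_drug_sets <- function(coll) {
  ids <- coll$demo$report_id
  sets <- split(coll$drugs$drug_name, coll$drugs$report_id)
  lapply(ids, function(id) unique(sets[[id]]))
}

oracle_single_counts <- function(coll, flags, drug) {
  sets <- report_drug_sets(coll)
  ids <- coll$demo$report_id
  a <- b <- cc <- d <- 0
  for (i in seq_along(ids)) {
    if (length(sets[[i]]) == 0) next  # no exposure information
    expos <- drug %in% sets[[i]]
    ev <- unname(flags[ids[i]])
    if (expos && ev) a <- a + 1
    else if (expos) b <- b + 1
    else if (ev) cc <- cc + 1
    else d <- d + 1
  }
  list(a = a, b = b, c = cc, d = d)
}

oracle_pair_cells <- function(coll, flags, d1, d2) {
  sets <- report_drug_sets(coll)
  ids <- coll$demo$report_id
  out <- c(n111 = 0, n110 = 0, n101 = 0, n100 = 0,
           n011 = 0, n010 = 0, n001 = 0, n000 = 0)
  for (i in seq_along(ids)) {
    if (length(sets[[i]]) == 0) next
    e1 <- d1 %in% sets[[i]]
    e2 <- d2 %in% sets[[i]]
    ev <- unname(flags[ids[i]])
    cell <- paste0("n", as.integer(e1), as.integer(e2), as.integer(ev))
    out[cell] <- out[cell] + 1
  }
  as.list(out)
}

# exhaustive pair enumeration over all drug pairs
oracle_eligible_pairs <- function(coll, flags, min_cases, min_drug_cases) {
  sets <- report_drug_sets(coll)
  ids <- coll$demo$report_id
  case_sets <- sets[unname(flags[ids])]
  drug_case_n <- table(unlist(case_sets))
  screened <- sort(names(drug_case_n)[drug_case_n >= min_drug_cases])
  out <- list()
  if (length(screened) >= 2) {
    for (i in seq_len(length(screened) - 1)) {
      for (j in (i + 1):length(screened)) {
        d1 <- screened[i]; d2 <- screened[j]
        n111 <- sum(vapply(case_sets,
                           function(s) d1 %in% s && d2 %in% s, TRUE))
        if (n111 >= min_cases) {
          out[[length(out) + 1]] <- c(drug_low = d1, drug_high = d2,
                                      n111 = n111)
        }
      }
    }
  }
  out
}

# literal statistic transcriptions --------------------------------------

o_ror <- function(a, b, cc, d) {
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  est <- a * d / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  c(ror = est, lo = exp(log(est) - 1.96 * se), hi = exp(log(est) + 1.96 * se))
}

o_gshrunk <- function(k, n) (k + 0.5) / (n + 0.5)

o_baseline <- function(x, variant) {
  g00 <- o_gshrunk(x$n001, x$n001 + x$n000)
  g10 <- o_gshrunk(x$n101, x$n101 + x$n100)
  g01 <- o_gshrunk(x$n011, x$n011 + x$n010)
  fb <- FALSE
  if (variant == "noren") {
    h <- 1 / (1 - g10) + 1 / (1 - g01) - 1 / (1 - g00)
    if (h > 1) g11 <- 1 - 1 / h else { g11 <- max(g10, g01); fb <- TRUE }
  } else if (variant == "reciprocal") {
    r <- 1 / g10 + 1 / g01 - 1 / g00
    if (r > 0) g11 <- 1 / r else { g11 <- max(g10, g01); fb <- TRUE }
  } else {
    g11 <- max(g10, g01)
  }
  g11 <- min(g11, 1)
  list(g11 = g11, e111 = g11 * (x$n111 + x$n110), fallback = fb)
}

o_omega <- function(n111, e111) {
  om <- log((n111 + 0.5) / (e111 + 0.5)) / log(2)
  c(omega = om, omega025 = om - 3.3 / sqrt(n111) - 2 / n111^0.75)
}

o_chi <- function(x, e111) {
  n11p <- x$n111 + x$n110
  term <- max(abs(x$n111 - e111) - 0.5, 0)
  chi2 <- term^2 * (1 / e111 + 1 / (n11p - e111))
  if (x$n111 >= e111) sqrt(chi2) else -sqrt(chi2)
}

o_yates2x2 <- function(a, b, cc, d) {
  n <- a + b + cc + d
  n * max(abs(a * d - b * cc) - n / 2, 0)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

o_crr <- function(x) {
  k <- if (x$n001 == 0) 0.5 else 0
  n11p <- x$n111 + x$n110; n10p <- x$n101 + x$n100
  n01p <- x$n011 + x$n010; n00p <- x$n001 + x$n000
  ref <- (x$n001 + k) / (n00p + k)
  prr_combo <- ((x$n111 + k) / (n11p + k)) / ref
  prr10 <- ((x$n101 + k) / (n10p + k)) / ref
  prr01 <- ((x$n011 + k) / (n01p + k)) / ref
  list(prr_combo = prr_combo, prr10 = prr10, prr01 = prr01,
       crr = prr_combo / max(prr10, prr01),
       chi2 = o_yates2x2(x$n111, x$n110, x$n001, x$n000))
}

o_additive <- function(x) {
  x$n111 / (x$n111 + x$n110) - x$n101 / (x$n101 + x$n100) -
    x$n011 / (x$n011 + x$n010) + x$n001 / (x$n001 + x$n000)
}

o_agreement <- function(f1, f2) {
  a <- sum(f1 == 1 & f2 == 1); b <- sum(f1 == 1 & f2 == 0)
  cc <- sum(f1 == 0 & f2 == 1); d <- sum(f1 == 0 & f2 == 0)
  n <- a + b + cc + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  list(a = a, b = b, c = cc, d = d,
       po = po, pe = pe, kappa = (po - pe) / (1 - pe),
       p_positive = 2 * a / (2 * a + b + cc),
       p_negative = 2 * d / (2 * d + b + cc))
}
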