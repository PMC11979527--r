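ref_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(drug1 = r[1], drug2 = r[2], source = r[3], severity = r[4])
  }))
}

test_that("reference loading canonicalizes pairs and collapses duplicates", {
  df <- ref_df(c("A", "B", "lexicomp", "X"),
               c("B", "A", "lexicomp", "X"),      # reversed duplicate
               c("A", "B", "drugscom", "Major"),
               c("C", "D", "drugscom", "Moderate"),
               c("c", "E", "lexicomp", "D"),
               c("E", "F", "lexicomp", "B"))
  expect_warning(ref <- load_reference(df), "collapsed")
  expect_equal(nrow(ref), 5)
  expect_true(all(ref$drug_low < ref$drug_high))
  expect_equal(sort(unique(ref$source)), c("drugscom", "lexicomp"))

  # empty file with header
  path <- tempfile(fileext = ".csv")
  writeLines("drug1,drug2,source,severity", path)
  expect_equal(nrow(load_reference(path)), 0)

  # vocabulary validation
  expect_error(load_reference(ref_df(c("A", "B", "micromedex", "X"))),
               "unknown reference source")
  expect_error(load_reference(ref_df(c("A", "B", "lexicomp", "Major"))),
               "invalid severity.*lexicomp")
  expect_error(load_reference(data.frame(drug1 = "A", drug2 = "B")),
               "missing required column")
})

test_that("annotation loading validates the tier vocabularies", {
  ann <- load_annotations(data.frame(drug = c("Amiodarone", "sotalol"),
                                     credible_meds = c("known", "possible"),
                                     uptodate = c("highest", "none")))
  expect_equal(ann$drug_name, c("amiodarone", "sotalol"))
  expect_error(load_annotations(data.frame(drug = "x", credible_meds = "high",
                                           uptodate = "none")),
               "invalid annotation tier")
})

# a small hand-built signal table: three consensus pairs, one evaluable
# all-negative pair, one pair with an unevaluable model
toy_signals <- function() {
  data.table::data.table(
    drug_low = c("a", "a", "b", "c", "d"),
    drug_high = c("b", "c", "c", "e", "e"),
    n111 = c(10L, 8L, 6L, 12L, 4L),
    n11p = 100L, e111 = 2, fallback_used = FALSE,
    omega = 1, omega025 = c(1, 1, 1, -1, 1),
    omega_flag = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    chi = 3, chi_flag = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    prr_combo = 5, chi2_combo = 50, crr = 3,
    crr_flag = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    contrast = 0.01,
    additive_flag = c(TRUE, TRUE, TRUE, FALSE, NA),
    consensus = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

test_that("the verification funnel partitions consensus pairs by indexing status", {
  sig <- toy_signals()
  ref <- load_reference(ref_df(c("a", "b", "lexicomp", "X"),
                               c("a", "b", "drugscom", "Major"),
                               c("a", "c", "lexicomp", "D"),
                               c("c", "e", "lexicomp", "C"),
                               c("c", "e", "drugscom", "Major")))
  fr <- classify_pairs(sig, ref)
  expect_equal(fr$funnel$detected_total, 3)
  expect_equal(fr$funnel$indexed_either, 2)
  expect_equal(fr$funnel$indexed_both, 1)
  expect_equal(fr$funnel$indexed_neither, 1)
  # funnel conservation
  expect_equal(fr$funnel$indexed_either + fr$funnel$indexed_neither,
               fr$funnel$detected_total)
  expect_true(fr$funnel$indexed_both <= fr$funnel$indexed_either)

  # c+e is indexed by both, evaluable with n111 >= 3, flagged by no model
  expect_equal(nrow(fr$negative_ddis), 1)
  expect_equal(fr$negative_ddis$drug_low, "c")
  expect_equal(fr$negative_ddis$drug_high, "e")

  # any-model detection widens the detected set
  fr_any <- classify_pairs(sig, ref, detected = "any")
  expect_equal(fr_any$funnel$detected_total, 4)  # d+e has an omega flag
})

test_that("classification ignores reference row and drug order", {
  sig <- toy_signals()
  ref1 <- load_reference(ref_df(c("a", "b", "lexicomp", "X"),
                                c("c", "a", "drugscom", "Major")))
  ref2 <- load_reference(ref_df(c("a", "c", "drugscom", "Major"),
                                c("b", "a", "lexicomp", "X")))
  f1 <- classify_pairs(sig, ref1)
  f2 <- classify_pairs(sig, ref2)
  expect_equal(f1$funnel, f2$funnel)
  expect_equal(f1$pairs, f2$pairs)
})

test_that("pairs with an unevaluable model never become negative DDIs", {
  sig <- toy_signals()
  # d+e: all four flags FALSE-or-NA, indexed by both -> still excluded
  ref <- load_reference(ref_df(c("d", "e", "lexicomp", "X"),
                               c("d", "e", "drugscom", "Major")))
  sig$omega_flag[5] <- FALSE; sig$chi_flag[5] <- FALSE
  sig$crr_flag[5] <- FALSE  # additive stays NA
  fr <- classify_pairs(sig, ref)
  expect_equal(nrow(fr$negative_ddis), 0)
})

test_that("drug degree tables respect the handshake identity and annotations", {
  sig <- toy_signals()
  deg <- annotate_drugs(sig)
  expect_equal(sum(deg$degree), 2 * sum(sig$consensus))
  expect_equal(deg$drug_name[1], "a")  # a is in 2 consensus pairs
  expect_equal(deg$degree[deg$drug_name == "a"], 2)
  ann <- load_annotations(data.frame(drug = "a", credible_meds = "known",
                                     uptodate = "highest"))
  deg2 <- annotate_drugs(sig, ann)
  expect_equal(deg2$credible_meds[deg2$drug_name == "a"], "known")
  expect_equal(deg2$credible_meds[deg2$drug_name == "b"], "none")
})
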