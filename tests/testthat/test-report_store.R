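test_that("flat dialect reader groups rows into reports and normalizes drugs", {
  path <- write_flat_fixture()
  coll <- read_reports(path, dialect = "flat_case_table")
  expect_s3_class(coll, "report_collection")
  expect_equal(n_reports(coll), 3L)
  # amiodarone listed twice in r1 (PS and C): one drug name, two role rows,
  # counted once in exposure
  r1 <- coll$drugs[coll$drugs$report_id == "r1", ]
  expect_equal(sort(unique(r1$drug_name)), c("amiodarone", "sotalol"))
  expect_equal(sort(r1$role_code[r1$drug_name == "amiodarone"]), c("C", "PS"))
  flags <- mark_cases(coll, TARGET_PT)
  ct <- single_drug_counts(coll, flags, "amiodarone")
  expect_equal(ct$a, 1L)
  expect_equal(ct$a + ct$b, 1L)  # exposure deduplicated
})

test_that("empty input with a valid header yields an empty collection", {
  path <- tempfile(fileext = ".csv")
  writeLines("report_id,drug_name,role_code,pt_code,reporter_type,sex,age,country,outcome",
             path)
  coll <- read_reports(path)
  expect_equal(n_reports(coll), 0L)
  expect_equal(sum(mark_cases(coll, TARGET_PT)), 0L)
})

test_that("schema and row-level validation fail loudly", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("report_id\tdrug_name\trole_code", "r1\tx\tPS"), path)
  expect_error(read_reports(path), "missing required column.*pt_code")

  bad_role <- sub("\tPS\t", "\tXX\t", flat_fixture_lines())
  path2 <- tempfile(fileext = ".tsv")
  writeLines(bad_role, path2)
  expect_error(read_reports(path2), "role_code.*r1")

  conflict <- c(flat_fixture_lines(),
                "r2\tdiazepam\tC\t10000002\tconsumer\tmale\t46\tjp\tother")
  path3 <- tempfile(fileext = ".tsv")
  writeLines(conflict, path3)
  expect_error(read_reports(path3), "conflicting demographics.*r2")
})

test_that("flat dialect round-trips a collection identically", {
  coll <- random_collection(n_reports = 80, n_drugs = 12, seed = 42)
  path <- tempfile(fileext = ".tsv")
  write_reports(coll, path)
  back <- read_reports(path)
  expect_same_collection(back, coll)
  # and writing again is byte-identical
  path2 <- tempfile(fileext = ".tsv")
  write_reports(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("FAERS-like multi-table dialect round-trips through the flat reader", {
  coll <- random_collection(n_reports = 60, n_drugs = 10, seed = 7)
  dir <- tempfile()
  write_reports(coll, dir, dialect = "faers_like_multi_table")
  back <- read_reports(dir, dialect = "faers_like_multi_table")
  expect_same_collection(back, coll)
  expect_error(read_reports(tempfile(), dialect = "faers_like_multi_table"),
               "expects a directory")
})

test_that("duplicate drug rows never change downstream counts", {
  coll <- random_collection(n_reports = 100, n_drugs = 10, seed = 3)
  flags <- mark_cases(coll, TARGET_PT)
  dup_drugs <- rbind(coll$drugs, coll$drugs)
  coll2 <- report_collection(coll$demo, dup_drugs, coll$reactions,
                             coll$outcomes)
  expect_same_collection(coll2, coll)
  p1 <- eligible_pairs(coll, flags, min_cases = 1, min_drug_cases = 1)
  p2 <- eligible_pairs(coll2, flags, min_cases = 1, min_drug_cases = 1)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
})

test_that("mark_cases flags exactly the reports carrying the target PT", {
  path <- write_flat_fixture()
  coll <- read_reports(path)
  flags <- mark_cases(coll, TARGET_PT)
  expect_equal(unname(flags), c(TRUE, FALSE, FALSE))
  expect_equal(names(flags), c("r1", "r2", "r3"))
  none <- mark_cases(coll, "99999999")
  expect_false(any(none))
  expect_error(mark_cases(coll, ""), "non-empty")
})

test_that("filter_by_reporter drops exactly the excluded types", {
  coll <- random_collection(n_reports = 50, seed = 11)
  tab <- table(coll$demo$reporter_type)
  kept <- filter_by_reporter(coll, c("consumer", "lawyer"))
  expect_equal(n_reports(kept),
               n_reports(coll) - sum(tab[c("consumer", "lawyer")], na.rm = TRUE))
  expect_false(any(kept$demo$reporter_type %in% c("consumer", "lawyer")))
  # identity and empty cases
  expect_same_collection(filter_by_reporter(coll, character()), coll)
  all_types <- unique(coll$demo$reporter_type)
  expect_equal(n_reports(filter_by_reporter(coll, all_types)), 0L)
  expect_error(filter_by_reporter(coll, "nurse"), "unknown reporter type")
})

test_that("reporter filtering commutes with case marking", {
  coll <- random_collection(n_reports = 120, seed = 5)
  flags_full <- mark_cases(coll, TARGET_PT)
  sub <- filter_by_reporter(coll, c("consumer", "unknown"))
  flags_sub <- mark_cases(sub, TARGET_PT)
  expect_equal(flags_sub, flags_full[names(flags_sub)])
})

test_that("restrict_to_role keeps matching drug entries and drops empty reports", {
  path <- write_flat_fixture()
  coll <- read_reports(path)
  only_i <- restrict_to_role(coll, "I")
  expect_equal(only_i$demo$report_id, "r3")
  expect_equal(only_i$drugs$drug_name, "quetiapine")
  # full role set is the identity on drug sets
  all_roles <- restrict_to_role(coll, c("PS", "SS", "C", "I"))
  expect_same_collection(all_roles, coll)
  expect_error(restrict_to_role(coll, character()), "non-empty")
  expect_error(restrict_to_role(coll, "Z"), "unknown role")
})

test_that("role restriction then pairing equals brute force on the subset", {
  coll <- random_collection(n_reports = 150, n_drugs = 8, seed = 13)
  ps_only <- restrict_to_role(coll, "PS")
  flags <- mark_cases(ps_only, TARGET_PT)
  got <- eligible_pairs(ps_only, flags, min_cases = 1, min_drug_cases = 1)
  want <- oracle_eligible_pairs(ps_only, flags, 1, 1)
  expect_equal(nrow(got), length(want))
  if (length(want)) {
    want_keys <- vapply(want, function(w) paste(w[["drug_low"]], w[["drug_high"]]), "")
    expect_equal(paste(got$drug_low, got$drug_high), sort(want_keys))
  }
})

test_that("synonym tables map trade names onto generics before counting", {
  path <- write_flat_fixture()
  syn <- data.frame(trade_name = "Quetiapine", generic = "seroquel-generic")
  coll <- read_reports(path, synonyms = syn)
  expect_true("seroquel-generic" %in% coll$drugs$drug_name)
  expect_false("quetiapine" %in% coll$drugs$drug_name)
})
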