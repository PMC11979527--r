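# Programmatic fixtures: no data files, everything built in code.

TARGET_PT <- "10044066"

# random report collection with moderate event prevalence, suitable for
# brute-force cross-checking
random_collection <- function(n_reports = 200, n_drugs = 30, seed = 1,
                              event_prob = 0.2, max_drugs_per_report = 5) {
  set.seed(seed)
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  ids <- sprintf("r%04d", seq_len(n_reports))
  drug_rows <- lapply(seq_len(n_reports), function(i) {
    k <- sample(1:max_drugs_per_report, 1)
    nm <- sample(drugs, k)
    data.frame(report_id = ids[i], drug_name = nm,
               role_code = sample(c("PS", "SS", "C", "I"), k, replace = TRUE))
  })
  drug_tab <- do.call(rbind, drug_rows)
  event <- runif(n_reports) < event_prob
  reac <- data.frame(
    report_id = ids,
    pt_code = ifelse(event, TARGET_PT, sprintf("10%06d", sample(1:20, n_reports, TRUE)))
  )
  demo <- data.frame(
    report_id = ids,
    reporter_type = sample(c("physician", "pharmacist", "other_health_professional",
                             "consumer", "lawyer", "unknown"), n_reports, TRUE),
    sex = sample(c("male", "female", "unknown"), n_reports, TRUE),
    age_years = ifelse(runif(n_reports) < 0.2, NA, sample(0:97, n_reports, TRUE)),
    country = sample(c("us", "jp", "other"), n_reports, TRUE)
  )
  outc <- data.frame(
    report_id = ids,
    outcome = sample(c("death", "life_threatening", "hospitalization", "other",
                       "unknown"), n_reports, TRUE)
  )
  report_collection(demo, drug_tab, reac, outc)
}

# tiny deterministic flat-dialect file contents (3 reports, 5 drug rows)
flat_fixture_lines <- function() {
  c(
    "report_id\tdrug_name\trole_code\tpt_code\treporter_type\tsex\tage\tcountry\toutcome",
    paste0("r1\tAMIODARONE \tPS\t", TARGET_PT, ";10000001\tphysician\tfemale\t71\tus\tdeath"),
    paste0("r1\tamiodarone\tC\t", TARGET_PT, ";10000001\tphysician\tfemale\t71\tus\tdeath"),
    paste0("r1\tSotalol\tSS\t", TARGET_PT, ";10000001\tphysician\tfemale\t71\tus\tdeath"),
    "r2\tcitalopram\tPS\t10000002\tconsumer\tmale\t45\tjp\tother",
    "r3\tQuetiapine\tI\t10000003\tpharmacist\tunknown\t\tus\thospitalization"
  )
}

write_flat_fixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(flat_fixture_lines(), path)
  path
}

# collections compare on content (data.table internals carry volatile
# attributes such as self-reference pointers and indices)
expect_same_collection <- function(a, b) {
  for (tab in c("demo", "drugs", "reactions", "outcomes")) {
    expect_equal(as.data.frame(a[[tab]]), as.data.frame(b[[tab]]),
                 label = paste0("a$", tab), expected.label = paste0("b$", tab))
  }
}

# pair_counts object straight from the eight cells
pc <- function(n111, n110, n101, n100, n011, n010, n001, n000,
               drug_low = "a", drug_high = "b") {
  tdpddi:::new_pair_counts(list(
    drug_low = drug_low, drug_high = drug_high,
    n111 = n111, n110 = n110, n101 = n101, n100 = n100,
    n011 = n011, n010 = n010, n001 = n001, n000 = n000
  ))
}

# swap the two drugs of a pair_counts (index permutation)
pc_swapped <- function(x) {
  pc(x$n111, x$n110, x$n011, x$n010, x$n101, x$n100, x$n001, x$n000,
     x$drug_low, x$drug_high)
}
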