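ROLE_CODES <- c("PS", "SS", "C", "I")
REPORTER_TYPES <- c("physician", "pharmacist", "other_health_professional",
                    "consumer", "lawyer", "unknown")
SEX_LEVELS <- c("male", "female", "unknown")
OUTCOME_LEVELS <- c("death", "life_threatening", "disability", "hospitalization",
                    "required_intervention", "other", "unknown")

#' Construct a report collection
#'
#' A `report_collection` holds case-level spontaneous reports as four
#' linked tables keyed by `report_id`: demographics (one row per report),
#' drug entries (report, normalized drug name, role code), reaction
#' preferred terms (PTs, opaque strings) and outcomes. The constructor
#' canonicalizes: drug names are normalized with [normalize_drug_name()],
#' exact duplicate rows are collapsed (a drug listed twice under the same
#' role counts once; two roles for one drug keep both role rows, but all
#' exposure counting uses the deduplicated per-report drug set), and rows
#' are sorted so that equal collections are byte-identical.
#'
#' @param demo data.frame with columns `report_id`, `reporter_type`, `sex`,
#'   `age_years`, `country` (one row per report).
#' @param drugs data.frame with columns `report_id`, `drug_name`, `role_code`.
#' @param reactions data.frame with columns `report_id`, `pt_code`.
#' @param outcomes data.frame with columns `report_id`, `outcome`.
#' @return an object of class `report_collection`.
#' @export
report_collection <- function(demo, drugs, reactions, outcomes) {
  demo <- as.data.table(demo)
  drugs <- as.data.table(drugs)
  reactions <- as.data.table(reactions)
  outcomes <- as.data.table(outcomes)

  demo[, report_id := as.character(report_id)]
  if (anyDuplicated(demo$report_id)) {
    dup <- unique(demo$report_id[duplicated(demo$report_id)])
    stop("duplicate report_id with conflicting demographics: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  demo[, reporter_type := map_to_domain(reporter_type, REPORTER_TYPES)]
  demo[, sex := map_to_domain(sex, SEX_LEVELS)]
  demo[, age_years := suppressWarnings(as.numeric(age_years))]
  demo[!is.na(age_years) & age_years < 0, age_years := NA_real_]
  demo[, country := fifelse(is.na(country) | trimws(country) == "",
                            "unknown", trimws(as.character(country)))]

  drugs[, report_id := as.character(report_id)]
  drugs[, drug_name := normalize_drug_name(drug_name)]
  if (any(drugs$drug_name == "")) {
    bad <- unique(drugs$report_id[drugs$drug_name == ""])
    stop("empty drug_name after normalization in report(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  drugs[, role_code := toupper(trimws(as.character(role_code)))]
  bad_role <- !drugs$role_code %in% ROLE_CODES
  if (any(bad_role)) {
    stop("unparseable role_code (allowed: PS, SS, C, I) in report(s): ",
         paste(head(unique(drugs$report_id[bad_role]), 5), collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(drugs$report_id, demo$report_id)
  if (length(orphan)) {
    stop("drug rows reference unknown report_id: ",
         paste(head(orphan, 5), collapse = ", "), call. = FALSE)
  }

  reactions[, report_id := as.character(report_id)]
  reactions[, pt_code := trimws(as.character(pt_code))]
  reactions <- reactions[!is.na(pt_code) & pt_code != ""]
  outcomes[, report_id := as.character(report_id)]
  outcomes[, outcome := map_to_domain(outcome, OUTCOME_LEVELS)]

  data.table::setcolorder(demo, c("report_id", "reporter_type", "sex",
                                  "age_years", "country"))
  data.table::setcolorder(drugs, c("report_id", "drug_name", "role_code"))
  demo <- unique(demo[, list(report_id, reporter_type, sex, age_years, country)])[order(report_id)]
  drugs <- unique(drugs[, list(report_id, drug_name, role_code)])[order(report_id, drug_name, role_code)]
  reactions <- unique(reactions[, list(report_id, pt_code)])[order(report_id, pt_code)]
  outcomes <- unique(outcomes[, list(report_id, outcome)])[order(report_id, outcome)]

  structure(
    list(demo = demo, drugs = drugs, reactions = reactions, outcomes = outcomes),
    class = "report_collection"
  )
}

map_to_domain <- function(x, domain) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | !x %in% domain] <- "unknown"
  x
}

#' @export
print.report_collection <- function(x, ...) {
  cat("<report_collection>\n")
  cat("  reports:            ", n_reports(x), "\n", sep = "")
  cat("  with >=1 drug entry:", sum(x$demo$report_id %in% x$drugs$report_id), "\n")
  cat("  distinct drugs:     ", uniqueN(x$drugs$drug_name), "\n", sep = "")
  cat("  distinct PTs:       ", uniqueN(x$reactions$pt_code), "\n", sep = "")
  invisible(x)
}

#' Number of reports in a collection
#' @param collection a `report_collection`.
#' @return integer count of reports.
#' @export
n_reports <- function(collection) nrow(collection$demo)

# reports carrying at least one drug entry form the analyzable universe N;
# drug-less reports carry no exposure information and are excluded from
# all contingency denominators.
analyzable_ids <- function(collection) {
  ids <- collection$demo$report_id
  ids[ids %in% unique(collection$drugs$report_id)]
}

# deduplicated per-report exposure table (report_id, drug_name)
exposure_table <- function(collection) {
  unique(collection$drugs[, list(report_id, drug_name)])
}

subset_reports <- function(collection, keep_ids) {
  structure(
    list(
      demo = collection$demo[report_id %in% keep_ids],
      drugs = collection$drugs[report_id %in% keep_ids],
      reactions = collection$reactions[report_id %in% keep_ids],
      outcomes = collection$outcomes[report_id %in% keep_ids]
    ),
    class = "report_collection"
  )
}

#' Read case-level spontaneous reports
#'
#' Reads a delimited report file (or FAERS-like multi-table directory),
#' validates it and returns a canonical [report_collection()].
#'
#' The `flat_case_table` dialect is a single UTF-8 delimited file (tab or
#' comma, auto-detected from the header line) with one row per report-drug
#' entry and columns `report_id`, `drug_name`, `role_code`, `pt_code`,
#' `reporter_type`, `sex`, `age`, `country`, `outcome`. `pt_code` and
#' `outcome` may be semicolon-separated lists, or PTs may be spread over
#' repeated rows. The `faers_like_multi_table` dialect is a directory of
#' five delimited files sharing `report_id` keys, mirroring the FAERS
#' quarterly ASCII tables: `demo` (`report_id`, `sex`, `age`, `country`),
#' `drug` (`report_id`, `drug_name`, `role_code`), `reac` (`report_id`,
#' `pt_code`), `outc` (`report_id`, `outcome`) and `rpsr` (`report_id`,
#' `reporter_type`), each as `<name>.tsv` or `<name>.csv`.
#'
#' Drug names are normalized (trim, case-fold); within-report duplicate
#' drug names are collapsed for counting; unknown categorical values map to
#' `"unknown"`. Role codes outside \{PS, SS, C, I\} and conflicting
#' demographics for one `report_id` are errors.
#'
#' @param path file (flat dialect) or directory (FAERS-like dialect).
#' @param dialect input layout, see Details.
#' @param synonyms optional trade-name to generic mapping: a data.frame (or
#'   CSV path) with columns `trade_name`, `generic`, applied after
#'   normalization.
#' @return a [report_collection()].
#' @export
read_reports <- function(path,
                         dialect = c("flat_case_table", "faers_like_multi_table"),
                         synonyms = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "flat_case_table") {
    collection <- read_flat(path)
  } else {
    collection <- read_faers_like(path)
  }
  if (!is.null(synonyms)) collection <- apply_synonyms(collection, synonyms)
  collection
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

require_columns <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop("missing required column(s) in ", what, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

split_multi <- function(dt, col) {
  out <- dt[, list(value = trimws(unlist(strsplit(as.character(get(col)), ";",
                                                  fixed = TRUE)))),
            by = report_id]
  out <- out[!is.na(value) & value != ""]
  setnames(out, "value", col)
  out
}

read_flat <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path, call. = FALSE)
  dt <- fread(path, sep = detect_sep(path), colClasses = "character",
              na.strings = c("NA", ""))
  required <- c("report_id", "drug_name", "role_code", "pt_code",
                "reporter_type", "sex", "age", "country", "outcome")
  require_columns(dt, required, "flat case table")
  if (nrow(dt) == 0L) {
    return(report_collection(
      demo = data.table(report_id = character(), reporter_type = character(),
                        sex = character(), age_years = numeric(),
                        country = character()),
      drugs = data.table(report_id = character(), drug_name = character(),
                         role_code = character()),
      reactions = data.table(report_id = character(), pt_code = character()),
      outcomes = data.table(report_id = character(), outcome = character())
    ))
  }
  demo_raw <- unique(dt[, list(report_id, reporter_type, sex, age, country)])
  if (anyDuplicated(demo_raw$report_id)) {
    dup <- unique(demo_raw$report_id[duplicated(demo_raw$report_id)])
    stop("duplicate report_id with conflicting demographics: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  setnames(demo_raw, "age", "age_years")
  report_collection(
    demo = demo_raw,
    drugs = dt[, list(report_id, drug_name, role_code)],
    reactions = split_multi(dt[, list(report_id, pt_code)], "pt_code"),
    outcomes = split_multi(dt[, list(report_id, outcome)], "outcome")
  )
}

faers_file <- function(dir, stem) {
  for (ext in c(".tsv", ".csv")) {
    f <- file.path(dir, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  stop("FAERS-like dialect: missing table '", stem, "' in ", dir, call. = FALSE)
}

read_faers_like <- function(path) {
  if (!dir.exists(path)) {
    stop("FAERS-like dialect expects a directory: ", path, call. = FALSE)
  }
  rd <- function(stem, cols) {
    f <- faers_file(path, stem)
    dt <- fread(f, sep = detect_sep(f), colClasses = "character",
                na.strings = c("NA", ""))
    require_columns(dt, cols, paste0(stem, " table"))
    dt[, cols, with = FALSE]
  }
  demo <- rd("demo", c("report_id", "sex", "age", "country"))
  drug <- rd("drug", c("report_id", "drug_name", "role_code"))
  reac <- rd("reac", c("report_id", "pt_code"))
  outc <- rd("outc", c("report_id", "outcome"))
  rpsr <- rd("rpsr", c("report_id", "reporter_type"))
  rpsr <- unique(rpsr)
  if (anyDuplicated(rpsr$report_id)) {
    dup <- unique(rpsr$report_id[duplicated(rpsr$report_id)])
    stop("conflicting reporter_type for report_id: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  demo <- unique(demo)
  demo <- merge(demo, rpsr, by = "report_id", all.x = TRUE)
  setnames(demo, "age", "age_years")
  report_collection(demo = demo, drugs = drug, reactions = reac, outcomes = outc)
}

apply_synonyms <- function(collection, synonyms) {
  if (is.character(synonyms) && length(synonyms) == 1L) {
    synonyms <- fread(synonyms, colClasses = "character")
  }
  synonyms <- as.data.table(synonyms)
  require_columns(synonyms, c("trade_name", "generic"), "synonym table")
  trade <- normalize_drug_name(synonyms$trade_name)
  generic <- normalize_drug_name(synonyms$generic)
  drugs <- copy(collection$drugs)
  hit <- match(drugs$drug_name, trade)
  drugs[!is.na(hit), drug_name := generic[hit[!is.na(hit)]]]
  report_collection(collection$demo, drugs, collection$reactions,
                    collection$outcomes)
}

#' Write a report collection
#'
#' Serializes a collection back to the flat case-table dialect (or the
#' FAERS-like directory dialect). Writing then re-reading yields an
#' identical collection.
#'
#' @param collection a [report_collection()].
#' @param path output file (flat) or directory (FAERS-like).
#' @param dialect output layout, see [read_reports()].
#' @return `path`, invisibly.
#' @export
write_reports <- function(collection, path,
                          dialect = c("flat_case_table", "faers_like_multi_table")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat_case_table") {
    pts <- collection$reactions[, list(pt_code = paste(sort(pt_code), collapse = ";")),
                                by = report_id]
    outc <- collection$outcomes[, list(outcome = paste(sort(outcome), collapse = ";")),
                                by = report_id]
    flat <- merge(collection$drugs, collection$demo, by = "report_id")
    flat <- merge(flat, pts, by = "report_id", all.x = TRUE)
    flat <- merge(flat, outc, by = "report_id", all.x = TRUE)
    setnames(flat, "age_years", "age")
    flat <- flat[, list(report_id, drug_name, role_code, pt_code,
                        reporter_type, sex, age, country, outcome)]
    setorder(flat, report_id, drug_name, role_code)
    fwrite(flat, path, sep = "\t", na = "", quote = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    demo <- copy(collection$demo)
    setnames(demo, "age_years", "age")
    fwrite(demo[, list(report_id, sex, age, country)],
           file.path(path, "demo.tsv"), sep = "\t", na = "", quote = FALSE)
    fwrite(demo[, list(report_id, reporter_type)],
           file.path(path, "rpsr.tsv"), sep = "\t", na = "", quote = FALSE)
    fwrite(collection$drugs, file.path(path, "drug.tsv"), sep = "\t", na = "",
           quote = FALSE)
    fwrite(collection$reactions, file.path(path, "reac.tsv"), sep = "\t", na = "",
           quote = FALSE)
    fwrite(collection$outcomes, file.path(path, "outc.tsv"), sep = "\t", na = "",
           quote = FALSE)
  }
  invisible(path)
}

#' Flag target-event cases
#'
#' @param collection a [report_collection()].
#' @param target_pt preferred-term code of the target adverse event
#'   (default `"10044066"`, torsades de pointes).
#' @return named logical vector aligned to the collection's reports; `TRUE`
#'   where the report lists the target PT.
#' @export
mark_cases <- function(collection, target_pt = "10044066") {
  target_pt <- trimws(as.character(target_pt))
  if (length(target_pt) != 1L || is.na(target_pt) || target_pt == "") {
    stop("target_pt must be a single non-empty PT code", call. = FALSE)
  }
  case_ids <- unique(collection$reactions[pt_code == target_pt, report_id])
  ids <- collection$demo$report_id
  setNames(ids %in% case_ids, ids)
}

#' Exclude reports by reporter type
#'
#' Sensitivity-analysis filter: drops reports whose reporter type is in
#' `excluded` (e.g. `c("consumer", "lawyer")` to exclude nonprofessional
#' reporters). The original collection is unchanged.
#'
#' @param collection a [report_collection()].
#' @param excluded character vector of reporter types to drop, a subset of
#'   `c("physician", "pharmacist", "other_health_professional", "consumer",
#'   "lawyer", "unknown")`.
#' @return a new [report_collection()].
#' @export
filter_by_reporter <- function(collection, excluded) {
  excluded <- as.character(excluded)
  bad <- setdiff(excluded, REPORTER_TYPES)
  if (length(bad)) {
    stop("unknown reporter type(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(REPORTER_TYPES, collapse = ", "), call. = FALSE)
  }
  keep <- collection$demo$report_id[!collection$demo$reporter_type %in% excluded]
  subset_reports(collection, keep)
}

#' Restrict drug entries to given role codes
#'
#' Keeps only drug entries whose FAERS role code is in `roles`; reports
#' left with no drug entries are dropped (they carry no exposure
#' information under the restriction). Use `roles = "I"` for the
#' interacting-drugs subset analysis.
#'
#' @param collection a [report_collection()].
#' @param roles non-empty subset of `c("PS", "SS", "C", "I")`.
#' @return a new [report_collection()].
#' @export
restrict_to_role <- function(collection, roles) {
  roles <- toupper(as.character(roles))
  if (length(roles) == 0L) stop("roles must be non-empty", call. = FALSE)
  bad <- setdiff(roles, ROLE_CODES)
  if (length(bad)) {
    stop("unknown role code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  drugs <- collection$drugs[role_code %in% roles]
  keep <- unique(drugs$report_id)
  structure(
    list(
      demo = collection$demo[report_id %in% keep],
      drugs = drugs,
      reactions = collection$reactions[report_id %in% keep],
      outcomes = collection$outcomes[report_id %in% keep]
    ),
    class = "report_collection"
  )
}
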