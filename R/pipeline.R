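OUTCOME_SEVERITY_ORDER <- c("death", "life_threatening", "disability",
                            "hospitalization", "required_intervention",
                            "other", "unknown")

age_band_of <- function(age) {
  fifelse(is.na(age), "unknown",
    fifelse(age < 20, "0-19",
      fifelse(age < 40, "20-39",
        fifelse(age < 60, "40-59",
          fifelse(age < 80, "60-79", "80+")))))
}

#' Demographic summary of target-event cases
#'
#' Tabulates the case reports by sex, age band (0-19, 20-39, 40-59,
#' 60-79, >=80, unknown; band edges inclusive of the lower bound),
#' severity outcome (worst outcome per report, ordered death >
#' life-threatening > disability > hospitalization > required
#' intervention > other > unknown), reporter type and country, each with
#' count and half-up-rounded percentage of total cases. Two derived rows
#' are appended: `older_than_60` (bands 60-79 and >=80) and
#' `nonprofessional` (consumer + lawyer reporters).
#'
#' @param collection a [report_collection()].
#' @param case_flags named logical vector from [mark_cases()].
#' @return a `data.table` of class `demographics_table` with columns
#'   `dimension`, `category`, `count`, `pct`, plus attribute `n_cases`.
#' @export
summarize_demographics <- function(collection, case_flags) {
  case_ids <- names(case_flags)[case_flags]
  n_cases <- length(case_ids)
  if (n_cases == 0L) stop("no target-event cases to summarize", call. = FALSE)
  demo <- collection$demo[report_id %in% case_ids]

  tab_dim <- function(values, dimension, levels) {
    counts <- table(factor(values, levels = levels))
    data.table(dimension = dimension, category = names(counts),
               count = as.integer(counts),
               pct = percentage(as.integer(counts), n_cases))
  }

  sex_tab <- tab_dim(demo$sex, "sex", SEX_LEVELS)
  age_tab <- tab_dim(age_band_of(demo$age_years), "age_band", AGE_BANDS)

  # worst outcome per case report
  outc <- collection$outcomes[report_id %in% case_ids]
  missing_outc <- setdiff(case_ids, outc$report_id)
  if (length(missing_outc)) {
    outc <- rbindlist(list(outc, data.table(report_id = missing_outc,
                                            outcome = "unknown")))
  }
  outc[, sev_rank := match(outcome, OUTCOME_SEVERITY_ORDER)]
  worst <- outc[, list(outcome = OUTCOME_SEVERITY_ORDER[min(sev_rank)]),
                by = report_id]
  sev_tab <- tab_dim(worst$outcome, "severity", OUTCOME_SEVERITY_ORDER)

  rep_tab <- tab_dim(demo$reporter_type, "reporter", REPORTER_TYPES)
  country_levels <- sort(unique(demo$country))
  ctry_tab <- tab_dim(demo$country, "country", country_levels)

  older <- sum(age_tab[category %in% c("60-79", "80+"), count])
  nonprof <- sum(rep_tab[category %in% c("consumer", "lawyer"), count])
  derived <- data.table(
    dimension = "derived",
    category = c("older_than_60", "nonprofessional"),
    count = c(older, nonprof),
    pct = percentage(c(older, nonprof), n_cases)
  )

  out <- rbindlist(list(sex_tab, age_tab, sev_tab, rep_tab, ctry_tab, derived))
  setattr(out, "n_cases", n_cases)
  structure(out, class = c("demographics_table", class(out)))
}

#' Single-drug reporting odds ratios for screened drugs
#'
#' Computes [reporting_odds_ratio()] for every drug appearing in at least
#' `min_drug_cases` case reports.
#'
#' @inheritParams summarize_demographics
#' @param min_drug_cases drug-level screen (default 3).
#' @param min_cases case threshold inside the ROR positivity criterion.
#' @return a `data.table`: `drug_name`, `a`, `ror`, `ci_low`, `ci_high`,
#'   `flag`, sorted by `a` descending.
#' @export
single_drug_ror_table <- function(collection, case_flags, min_drug_cases = 3,
                                  min_cases = 3) {
  ids <- analyzable_ids(collection)
  N <- length(ids)
  case_ids <- intersect(names(case_flags)[case_flags], ids)
  n_case <- length(case_ids)
  expo <- exposure_table(collection)[report_id %in% ids]
  per_drug <- expo[, list(n_exposed = .N,
                          a = sum(report_id %in% case_ids)), by = drug_name]
  screened <- per_drug[a >= min_drug_cases][order(drug_name)]
  rows <- lapply(seq_len(nrow(screened)), function(i) {
    ct <- list(a = screened$a[i], b = screened$n_exposed[i] - screened$a[i],
               c = n_case - screened$a[i],
               d = N - screened$n_exposed[i] - (n_case - screened$a[i]))
    r <- reporting_odds_ratio(ct, min_cases = min_cases)
    data.table(drug_name = screened$drug_name[i], a = r$n_cases, ror = r$ror,
               ci_low = r$ci_low, ci_high = r$ci_high, flag = r$flag)
  })
  out <- if (length(rows)) rbindlist(rows) else
    data.table(drug_name = character(), a = integer(), ror = numeric(),
               ci_low = numeric(), ci_high = numeric(), flag = logical())
  setorder(out, -a, drug_name)
  out[]
}

#' Run the full DDI signal-detection pipeline
#'
#' Orchestrates ingest (or synthetic generation), case marking, the
#' demographic summary, single-drug RORs, pair enumeration, the four DDI
#' models with consensus, the inter-model agreement matrix, compendium
#' verification and the sensitivity re-analysis excluding nonprofessional
#' reporters, and optionally writes all outputs as delimited text with a
#' YAML run manifest.
#'
#' @param reports a [report_collection()], or a path readable by
#'   [read_reports()]; alternatively supply `config`.
#' @param config a [synthetic_config()] to generate reports from (used
#'   when `reports` is `NULL`).
#' @param target_pt target event PT code.
#' @param reference optional compendium table ([load_reference()] input).
#' @param annotations optional drug annotations ([load_annotations()]
#'   input).
#' @param min_cases pair-level threshold on `n111` (default 3).
#' @param min_drug_cases drug-level case screen (default 3).
#' @param variant Omega/chi baseline variant (see
#'   [no_interaction_baseline()]).
#' @param dialect input dialect when `reports` is a path.
#' @param sensitivity_exclude reporter types excluded in the sensitivity
#'   re-analysis (default consumer and lawyer; set `NULL` to skip).
#' @param out_dir optional output directory for the delimited files
#'   (`demographics.tsv`, `single_drug_ror.tsv`, `pairs_counts.tsv`,
#'   `signals.tsv`, `agreement.tsv`, `funnel.tsv`, `negative_ddis.tsv`,
#'   `drug_degrees.tsv`, `edges.tsv`, `manifest.yaml`).
#' @param seed seed recorded in the manifest and used for synthetic
#'   generation.
#' @return a list of class `ddi_pipeline_result` with elements
#'   `collection`, `case_flags`, `demographics`, `ror`, `pairs`,
#'   `signals`, `agreement`, `funnel` (or `NULL`), `drug_degrees`,
#'   `edges`, `sensitivity` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(reports = NULL, config = NULL,
                         target_pt = "10044066", reference = NULL,
                         annotations = NULL, min_cases = 3,
                         min_drug_cases = 3,
                         variant = c("noren", "reciprocal", "max"),
                         dialect = "flat_case_table",
                         sensitivity_exclude = c("consumer", "lawyer"),
                         out_dir = NULL, seed = NULL) {
  variant <- match.arg(variant)
  input_desc <- list()
  if (is.null(reports)) {
    if (is.null(config)) stop("supply either reports or config", call. = FALSE)
    seed <- seed %||% config$seed
    collection <- generate_reports(config, seed = seed)
    input_desc$source <- "synthetic"
    input_desc$n_drawn <- config$n_reports
  } else if (inherits(reports, "report_collection")) {
    collection <- reports
    input_desc$source <- "collection"
  } else {
    input_desc$source <- "file"
    input_desc$path <- reports
    input_desc$md5 <- unname(tools::md5sum(reports)[1])
    collection <- read_reports(reports, dialect = dialect)
  }
  if (!is.null(reference) &&
      !all(c("drug_low", "drug_high") %in% names(reference))) {
    reference <- load_reference(reference)
  }
  if (!is.null(annotations) && !"drug_name" %in% names(annotations)) {
    annotations <- load_annotations(annotations)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_core <- function(coll) {
    flags <- stage("mark_cases", mark_cases(coll, target_pt))
    pairs <- stage("eligible_pairs",
                   eligible_pairs(coll, flags, min_cases = min_cases,
                                  min_drug_cases = min_drug_cases))
    signals <- stage("run_all_models",
                     run_all_models(pairs, min_cases = min_cases,
                                    variant = variant))
    list(flags = flags, pairs = pairs, signals = signals)
  }

  core <- run_core(collection)
  demographics <- stage("summarize_demographics",
                        summarize_demographics(collection, core$flags))
  ror <- stage("single_drug_ror",
               single_drug_ror_table(collection, core$flags,
                                     min_drug_cases = min_drug_cases,
                                     min_cases = min_cases))
  agreement <- if (nrow(core$signals)) {
    stage("agreement_matrix", agreement_matrix(core$signals))
  } else NULL
  funnel <- if (!is.null(reference)) {
    stage("classify_pairs",
          classify_pairs(core$signals, reference, min_cases = min_cases))
  } else NULL
  degrees <- stage("annotate_drugs", annotate_drugs(core$signals, annotations))
  edges <- core$signals[consensus == TRUE,
                        list(drug_low, drug_high, n111)]

  sensitivity <- NULL
  if (!is.null(sensitivity_exclude) && length(sensitivity_exclude)) {
    sens_coll <- stage("filter_by_reporter",
                       filter_by_reporter(collection, sensitivity_exclude))
    sens_core <- run_core(sens_coll)
    main_set <- core$signals[consensus == TRUE,
                             paste(drug_low, drug_high, sep = " + ")]
    sens_set <- sens_core$signals[consensus == TRUE,
                                  paste(drug_low, drug_high, sep = " + ")]
    sensitivity <- list(
      excluded = sensitivity_exclude,
      n_reports = n_reports(sens_coll),
      signals = sens_core$signals,
      consensus_main = main_set,
      consensus_sensitivity = sens_set,
      dropped = setdiff(main_set, sens_set),
      gained = setdiff(sens_set, main_set)
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tdpddi")),
    input = input_desc,
    target_pt = target_pt,
    thresholds = list(min_cases = min_cases, min_drug_cases = min_drug_cases),
    formula_variants = list(omega_baseline = variant,
                            ror_zero_cells = "haldane_anscombe_0.5",
                            crr_reference_stratum = "neither_drug"),
    sensitivity_excluded_reporters = as.list(sensitivity_exclude %||% list()),
    seed = seed,
    n_reports = n_reports(collection),
    n_cases = sum(core$flags),
    n_eligible_pairs = nrow(core$pairs)
  )

  result <- structure(list(
    collection = collection, case_flags = core$flags,
    demographics = demographics, ror = ror, pairs = core$pairs,
    signals = core$signals, agreement = agreement, funnel = funnel,
    drug_degrees = degrees, edges = edges, sensitivity = sensitivity,
    manifest = manifest
  ), class = "ddi_pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  # partial outputs are removed if any write fails
  on.exit({
    if (length(written) && !isTRUE(attr(written, "done"))) {
      unlink(file.path(out_dir, written))
    }
  })
  wr <- function(x, name) {
    fwrite(x, file.path(out_dir, name), sep = "\t", na = "", quote = FALSE)
    written <<- c(written, name)
  }
  wr(result$demographics, "demographics.tsv")
  wr(result$ror, "single_drug_ror.tsv")
  wr(result$pairs, "pairs_counts.tsv")
  wr(result$signals, "signals.tsv")
  if (!is.null(result$agreement)) wr(result$agreement, "agreement.tsv")
  if (!is.null(result$funnel)) {
    wr(result$funnel$funnel, "funnel.tsv")
    wr(result$funnel$negative_ddis, "negative_ddis.tsv")
  }
  wr(result$drug_degrees, "drug_degrees.tsv")
  wr(result$edges, "edges.tsv")
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  written <- c(written, "manifest.yaml")
  attr(written, "done") <- TRUE
  invisible(out_dir)
}

#' @export
print.ddi_pipeline_result <- function(x, ...) {
  cat("<ddi_pipeline_result>\n")
  cat("  reports:        ", n_reports(x$collection), "\n", sep = "")
  cat("  cases:          ", sum(x$case_flags), "\n", sep = "")
  cat("  eligible pairs: ", nrow(x$pairs), "\n", sep = "")
  cat("  consensus:      ", sum(x$signals$consensus), "\n", sep = "")
  if (!is.null(x$sensitivity)) {
    cat("  sensitivity consensus: ",
        length(x$sensitivity$consensus_sensitivity), " (",
        length(x$sensitivity$dropped), " dropped, ",
        length(x$sensitivity$gained), " gained)\n", sep = "")
  }
  invisible(x)
}

utils::globalVariables(c("sev_rank", "category", "count", "a"))
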