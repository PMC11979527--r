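REFERENCE_SOURCES <- c("lexicomp", "drugscom")
SEVERITY_CLASSES <- list(
  lexicomp = c("X", "D", "C", "B"),
  drugscom = c("Major", "Moderate", "Minor")
)
CREDIBLE_MEDS_TIERS <- c("known", "possible", "conditional", "none")
UPTODATE_TIERS <- c("highest", "moderate", "low", "none")

#' Load a DDI reference compendium table
#'
#' Reads a CSV with columns `drug1`, `drug2`, `source`, `severity`
#' emulating compendium interaction records (sources `lexicomp` with
#' severity classes X/D/C/B, `drugscom` with Major/Moderate/Minor).
#' Pair keys are canonicalized (drug order within a row is irrelevant) and
#' duplicate (pair, source) records are collapsed with a warning.
#' Severity vocabularies are validated but never ordered or interpreted.
#'
#' @param path CSV file path, or a data.frame with the same columns.
#' @return a `data.table` with columns `drug_low`, `drug_high`, `source`,
#'   `severity`, unique on (pair, source).
#' @export
load_reference <- function(path) {
  ref <- if (is.character(path)) {
    if (!file.exists(path)) stop("reference file does not exist: ", path,
                                 call. = FALSE)
    fread(path, colClasses = "character")
  } else {
    as.data.table(path)
  }
  require_columns(ref, c("drug1", "drug2", "source", "severity"),
                  "reference table")
  if (nrow(ref) == 0L) {
    return(data.table(drug_low = character(), drug_high = character(),
                      source = character(), severity = character()))
  }
  ref[, drug1 := normalize_drug_name(drug1)]
  ref[, drug2 := normalize_drug_name(drug2)]
  ref[, source := tolower(trimws(source))]
  ref[, severity := trimws(severity)]
  bad_src <- !ref$source %in% REFERENCE_SOURCES
  if (any(bad_src)) {
    stop("unknown reference source(s): ",
         paste(unique(ref$source[bad_src]), collapse = ", "),
         "; allowed: ", paste(REFERENCE_SOURCES, collapse = ", "),
         call. = FALSE)
  }
  for (src in REFERENCE_SOURCES) {
    allowed <- SEVERITY_CLASSES[[src]]
    sel <- ref$source == src
    # case-insensitive match, stored in canonical case
    idx <- match(tolower(ref$severity[sel]), tolower(allowed))
    if (anyNA(idx)) {
      stop("invalid severity for source '", src, "': ",
           paste(unique(ref$severity[sel][is.na(idx)]), collapse = ", "),
           "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
    }
    ref$severity[sel] <- allowed[idx]
  }
  key <- pair_key(ref$drug1, ref$drug2)
  ref[, drug_low := key$drug_low]
  ref[, drug_high := key$drug_high]
  ref <- ref[, list(drug_low, drug_high, source, severity)]
  n_dup <- nrow(ref) - uniqueN(ref[, list(drug_low, drug_high, source)])
  if (n_dup > 0) {
    warning(n_dup, " duplicated (pair, source) reference record(s) collapsed",
            call. = FALSE)
    ref <- unique(ref, by = c("drug_low", "drug_high", "source"))
  } else {
    ref <- unique(ref)
  }
  setorder(ref, drug_low, drug_high, source)
  ref[]
}

#' Load drug-level risk annotations
#'
#' Reads a CSV with columns `drug`, `credible_meds` (tiers known /
#' possible / conditional / none) and `uptodate` (highest / moderate /
#' low / none).
#'
#' @param path CSV file path, or a data.frame with the same columns.
#' @return a `data.table` with columns `drug_name`, `credible_meds`,
#'   `uptodate`.
#' @export
load_annotations <- function(path) {
  ann <- if (is.character(path)) fread(path, colClasses = "character")
         else as.data.table(path)
  require_columns(ann, c("drug", "credible_meds", "uptodate"),
                  "annotation table")
  ann[, drug := normalize_drug_name(drug)]
  ann[, credible_meds := tolower(trimws(credible_meds))]
  ann[, uptodate := tolower(trimws(uptodate))]
  bad_cm <- !ann$credible_meds %in% CREDIBLE_MEDS_TIERS
  bad_ut <- !ann$uptodate %in% UPTODATE_TIERS
  if (any(bad_cm) || any(bad_ut)) {
    stop("invalid annotation tier(s); credible_meds allows ",
         paste(CREDIBLE_MEDS_TIERS, collapse = "/"), ", uptodate allows ",
         paste(UPTODATE_TIERS, collapse = "/"), call. = FALSE)
  }
  out <- unique(ann[, list(drug_name = drug, credible_meds, uptodate)])
  setorder(out, drug_name)
  out[]
}

#' Verify detected pairs against reference compendia
#'
#' The signal-verification funnel: each detected pair (by default the
#' all-four consensus) is labeled by compendium indexing status
#' (lexicomp only / drugscom only / both / neither), and every reference
#' pair that is indexed by both sources, evaluable (`n111 >= min_cases`
#' and all four models evaluable) yet flagged by no model is listed as a
#' negative-DDI candidate -- a documented interaction with no
#' disproportionality support, of interest for alert-fatigue reduction.
#'
#' @param signals a `ddi_signals` table from [run_all_models()].
#' @param reference a reference table from [load_reference()].
#' @param detected `"consensus"` (default, all four models) or `"any"`
#'   (at least one model flag).
#' @param min_cases evaluability threshold on `n111` for negative-DDI
#'   candidates (default 3).
#' @return list of class `funnel_report`: `funnel` (category counts),
#'   `pairs` (per-pair labels for detected pairs) and `negative_ddis`.
#' @export
classify_pairs <- function(signals, reference,
                           detected = c("consensus", "any"), min_cases = 3) {
  detected <- match.arg(detected)
  sig <- as.data.table(signals)
  det <- if (detected == "consensus") {
    sig[consensus == TRUE]
  } else {
    sig[rowSums(cbind(sig$omega_flag, sig$chi_flag, sig$crr_flag,
                      sig$additive_flag) == TRUE, na.rm = TRUE) > 0]
  }
  ref_pairs <- unique(reference[, list(drug_low, drug_high, source)])
  in_source <- function(dl, dh, src) {
    paste(dl, dh, sep = "\r") %in%
      ref_pairs[source == src, paste(drug_low, drug_high, sep = "\r")]
  }
  lex <- in_source(det$drug_low, det$drug_high, "lexicomp")
  drc <- in_source(det$drug_low, det$drug_high, "drugscom")
  status <- fifelse(lex & drc, "both",
                    fifelse(lex, "lexicomp_only",
                            fifelse(drc, "drugscom_only", "neither")))
  pairs <- det[, list(drug_low, drug_high, n111)]
  pairs[, indexed_lexicomp := lex]
  pairs[, indexed_drugscom := drc]
  pairs[, index_status := status]

  funnel <- data.table(
    detected_total = nrow(det),
    indexed_lexicomp = sum(lex),
    indexed_drugscom = sum(drc),
    indexed_either = sum(lex | drc),
    indexed_both = sum(lex & drc),
    indexed_neither = sum(!lex & !drc)
  )

  # negative DDIs: indexed by both sources, evaluable, flagged by no model
  both_idx <- ref_pairs[, .N, by = list(drug_low, drug_high)][N >= 2L]
  ev <- sig[n111 >= min_cases &
              !is.na(omega_flag) & !is.na(chi_flag) &
              !is.na(crr_flag) & !is.na(additive_flag)]
  neg <- merge(ev, both_idx[, list(drug_low, drug_high)],
               by = c("drug_low", "drug_high"))
  neg <- neg[omega_flag == FALSE & chi_flag == FALSE & crr_flag == FALSE &
               additive_flag == FALSE,
             list(drug_low, drug_high, n111, omega025, chi, crr, contrast)]
  setorder(neg, drug_low, drug_high)

  structure(list(funnel = funnel, pairs = pairs, negative_ddis = neg,
                 detected = detected),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report> (detected = ", x$detected, ")\n", sep = "")
  print(x$funnel)
  cat("negative-DDI candidates:", nrow(x$negative_ddis), "\n")
  invisible(x)
}

#' Per-drug interaction degree table
#'
#' For each drug involved in a consensus-detected pair: the number of
#' consensus partners (degree), the total co-exposed case count over its
#' pairs, and (when annotations are supplied) its drug-level risk tiers.
#' Sorted by degree descending.
#'
#' @param signals a `ddi_signals` table from [run_all_models()].
#' @param annotations optional table from [load_annotations()].
#' @return a `data.table` with columns `drug_name`, `degree`,
#'   `total_n111` and, if annotated, `credible_meds`, `uptodate`.
#' @export
annotate_drugs <- function(signals, annotations = NULL) {
  det <- as.data.table(signals)[consensus == TRUE]
  long <- rbindlist(list(
    det[, list(drug_name = drug_low, n111)],
    det[, list(drug_name = drug_high, n111)]
  ))
  if (nrow(long) == 0L) {
    out <- data.table(drug_name = character(), degree = integer(),
                      total_n111 = integer())
  } else {
    out <- long[, list(degree = .N, total_n111 = sum(n111)), by = drug_name]
  }
  if (!is.null(annotations)) {
    out <- merge(out, annotations, by = "drug_name", all.x = TRUE)
    out[is.na(credible_meds), credible_meds := "none"]
    out[is.na(uptodate), uptodate := "none"]
  }
  setorder(out, -degree, drug_name)
  out[]
}

utils::globalVariables(c("indexed_lexicomp", "indexed_drugscom", "index_status",
                         "omega_flag", "chi_flag", "crr_flag", "additive_flag",
                         "omega025", "chi", "crr", "contrast", "degree",
                         "credible_meds", "uptodate", "drug1", "drug2", "drug",
                         "value", "n_excluded"))
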