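AGE_BANDS <- c("0-19", "20-39", "40-59", "60-79", "80+", "unknown")

#' Build a synthetic report-collection configuration
#'
#' Describes a FAERS-like population with known ground truth: per-drug
#' marginal exposure probabilities and multiplicative single-drug effects
#' on the event probability, plus designated drug pairs carrying a
#' co-prescription boost (extra probability of the partner given one
#' member present) and a multiplicative interaction effect beyond the two
#' single-drug effects (`interaction_multiplier = 1` means no
#' interaction; `> 1` synergy; `< 1` antagonism).
#'
#' @param n_reports number of reports to draw (reports ending up with no
#'   drug entry are discarded; spontaneous reports always carry a drug).
#' @param baseline_event_prob event probability of an unexposed report.
#' @param drugs data.frame with columns `name`, `exposure_prob` in (0,1),
#'   `risk_multiplier` > 0.
#' @param pairs data.frame (possibly empty) with columns `drug1`, `drug2`,
#'   `corx_boost` in \[0,1\], `interaction_multiplier` > 0 and an optional
#'   free-text `label`; each drug may belong to at most one pair.
#' @param reporter_distribution named probability vector over reporter
#'   types (must sum to 1).
#' @param sex_distribution,age_band_distribution,country_distribution,outcome_distribution
#'   named probability vectors for the demographics model (age bands
#'   `r paste(AGE_BANDS, collapse=", ")`).
#' @param target_pt PT code assigned to event reports.
#' @param pt_pool non-target PT codes used for background reactions.
#' @param interacting_role_prob probability that a co-exposed designated
#'   pair on a case report is coded with role `I` (interacting).
#' @param seed integer seed fixing the full generation stream.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports,
                             baseline_event_prob,
                             drugs,
                             pairs = NULL,
                             reporter_distribution = c(
                               physician = 0.36, pharmacist = 0.11,
                               other_health_professional = 0.39,
                               consumer = 0.051, lawyer = 0.017,
                               unknown = 0.072),
                             sex_distribution = c(
                               male = 0.324, female = 0.557, unknown = 0.119),
                             age_band_distribution = c(
                               "0-19" = 0.042, "20-39" = 0.145,
                               "40-59" = 0.234, "60-79" = 0.277,
                               "80+" = 0.106, "unknown" = 0.196),
                             country_distribution = c(
                               us = 0.414, jp = 0.047, cn = 0.019,
                               other = 0.445, unknown = 0.075),
                             outcome_distribution = c(
                               death = 0.084, life_threatening = 0.395,
                               disability = 0.001, hospitalization = 0.304,
                               required_intervention = 0.004, other = 0.206,
                               unknown = 0.006),
                             target_pt = "10044066",
                             pt_pool = sprintf("100%05d", 1:30),
                             interacting_role_prob = 0.5,
                             seed = 1L) {
  drugs <- as.data.table(drugs)
  require_columns(drugs, c("name", "exposure_prob", "risk_multiplier"),
                  "drug specification")
  if (nrow(drugs) == 0L) stop("drug list must be non-empty", call. = FALSE)
  drugs[, name := normalize_drug_name(name)]
  if (anyDuplicated(drugs$name)) stop("duplicate drug names", call. = FALSE)
  if (any(drugs$exposure_prob <= 0 | drugs$exposure_prob >= 1)) {
    stop("exposure_prob must be in (0, 1)", call. = FALSE)
  }
  if (any(drugs$risk_multiplier <= 0)) {
    stop("risk_multiplier must be positive", call. = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- data.table(drug1 = character(), drug2 = character(),
                        corx_boost = numeric(),
                        interaction_multiplier = numeric(),
                        label = character())
  }
  pairs <- as.data.table(pairs)
  require_columns(pairs, c("drug1", "drug2", "corx_boost",
                           "interaction_multiplier"), "pair specification")
  if (!"label" %in% names(pairs)) pairs[, label := ""]
  pairs[, drug1 := normalize_drug_name(drug1)]
  pairs[, drug2 := normalize_drug_name(drug2)]
  if (nrow(pairs)) {
    if (any(!c(pairs$drug1, pairs$drug2) %in% drugs$name)) {
      stop("pair members must be listed in drugs", call. = FALSE)
    }
    if (anyDuplicated(c(pairs$drug1, pairs$drug2))) {
      stop("each drug may belong to at most one designated pair",
           call. = FALSE)
    }
    if (any(pairs$corx_boost < 0 | pairs$corx_boost > 1)) {
      stop("corx_boost must be in [0, 1]", call. = FALSE)
    }
    if (any(pairs$interaction_multiplier <= 0)) {
      stop("interaction_multiplier must be positive", call. = FALSE)
    }
  }
  stopifnot(baseline_event_prob > 0, baseline_event_prob < 1, n_reports >= 1)
  check_dist <- function(d, nm, domain = NULL) {
    if (abs(sum(d) - 1) > 1e-6) stop(nm, " must sum to 1", call. = FALSE)
    if (!is.null(domain) && !all(names(d) %in% domain)) {
      stop(nm, " has unknown categories", call. = FALSE)
    }
  }
  check_dist(reporter_distribution, "reporter_distribution", REPORTER_TYPES)
  check_dist(sex_distribution, "sex_distribution", SEX_LEVELS)
  check_dist(age_band_distribution, "age_band_distribution", AGE_BANDS)
  check_dist(country_distribution, "country_distribution")
  check_dist(outcome_distribution, "outcome_distribution", OUTCOME_LEVELS)

  structure(list(
    n_reports = as.integer(n_reports),
    baseline_event_prob = baseline_event_prob,
    drugs = drugs[],
    pairs = pairs[],
    reporter_distribution = reporter_distribution,
    sex_distribution = sex_distribution,
    age_band_distribution = age_band_distribution,
    country_distribution = country_distribution,
    outcome_distribution = outcome_distribution,
    target_pt = as.character(target_pt),
    pt_pool = as.character(pt_pool),
    interacting_role_prob = interacting_role_prob,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' The published benchmark configuration
#'
#' A fixed desk-scale emulation of a spontaneous-reporting database used
#' throughout the test suite: 200,000 reports, baseline event probability
#' 5e-3, 60 drugs with log-spaced exposure probabilities in
#' \[0.002, 0.05\], a 93%/7% professional/nonprofessional reporter mix,
#' and four kinds of planted ground truth (all with co-prescription boost
#' 0.3):
#'
#' * 5 synergy pairs (`syn1`...`syn5`): individually inert drugs at
#'   mid-range exposure, interaction multiplier 8 -- the true DDI signals
#'   every model should recover;
#' * 5 no-synergy risk pairs (`risk1`...`risk5`): both members carry a
#'   3-fold single-drug risk but interaction multiplier 1, at low
#'   exposure -- their joint risk is multiplicative (9-fold), above the
#'   additive prediction (5-fold), so the point-estimate additive model
#'   over-detects them while the shrinkage-bounded Omega model should not;
#' * 1 antagonistic plant pair (`negctrl`): two widely used 3-fold-risk
#'   drugs with interaction multiplier 0.4, the compendium-indexed
#'   "negative DDI" analogue (joint reporting below even the additive
#'   expectation, so no model flags it);
#' * 5 pure co-prescription pairs (`corx1`...`corx5`): inert drugs that
#'   are merely co-prescribed, the null pairs on which additive
#'   over-detection shows up.
#'
#' Exposure probabilities are assigned to blocks deterministically by
#' prescription-frequency tier (risk pairs low, synergy mid, plant high);
#' see the methods vignette for the reasoning.
#'
#' @param seed seed stored in the config (default 1).
#' @return a [synthetic_config()].
#' @export
benchmark_default <- function(seed = 1L) {
  nd <- 60L
  probs <- exp(seq(log(0.002), log(0.05), length.out = nd))
  name <- sprintf("drug_%02d", seq_len(nd))
  risk_multiplier <- rep(1, nd)
  risk_idx <- 1:10                 # low-exposure risk-pair drugs
  syn_idx <- 26:35                 # mid-exposure synergy-pair drugs
  corx_idx <- 36:45                # co-prescription null-pair drugs
  plant_idx <- c(55L, 58L)         # high-exposure antagonistic plant
  risk_multiplier[risk_idx] <- 3
  risk_multiplier[plant_idx] <- 3
  drugs <- data.table(name = name, exposure_prob = probs,
                      risk_multiplier = risk_multiplier)
  mk_pairs <- function(idx, im, lab) {
    data.table(drug1 = name[idx[c(TRUE, FALSE)]],
               drug2 = name[idx[c(FALSE, TRUE)]],
               corx_boost = 0.3, interaction_multiplier = im,
               label = paste0(lab, seq_len(length(idx) / 2)))
  }
  pairs <- rbindlist(list(
    mk_pairs(syn_idx, 8, "syn"),
    mk_pairs(risk_idx, 1, "risk"),
    mk_pairs(corx_idx, 1, "corx"),
    data.table(drug1 = name[plant_idx[1]], drug2 = name[plant_idx[2]],
               corx_boost = 0.3, interaction_multiplier = 0.4,
               label = "negctrl")
  ))
  synthetic_config(n_reports = 200000L, baseline_event_prob = 5e-3,
                   drugs = drugs, pairs = pairs, seed = seed)
}

#' Ground-truth synergy pairs of a configuration
#'
#' @param config a [synthetic_config()].
#' @return a `data.table` with the canonicalized designated pairs having
#'   `interaction_multiplier > 1`, columns `drug_low`, `drug_high`,
#'   `interaction_multiplier`, `label`.
#' @export
ground_truth <- function(config) {
  p <- config$pairs[config$pairs$interaction_multiplier > 1]
  if (nrow(p) == 0L) {
    return(data.table(drug_low = character(), drug_high = character(),
                      interaction_multiplier = numeric(), label = character()))
  }
  key <- pair_key(p$drug1, p$drug2)
  out <- data.table(drug_low = key$drug_low, drug_high = key$drug_high,
                    interaction_multiplier = p$interaction_multiplier,
                    label = p$label)
  setorder(out, drug_low, drug_high)
  out[]
}

#' Analytic expected event prevalence of a configuration
#'
#' Expected event probability of a generated report (conditional on the
#' report carrying at least one drug, since drug-less draws are
#' discarded), computed exactly from the generative model by factorizing
#' over independent drug blocks; the 0.99 clamp is ignored (negligible
#' for rare-event configurations). Used as a binomial oracle for the
#' generator.
#'
#' @param config a [synthetic_config()].
#' @return expected prevalence (scalar).
#' @export
expected_event_prevalence <- function(config) {
  drugs <- config$drugs
  pairs <- config$pairs
  paired <- c(pairs$drug1, pairs$drug2)
  b <- config$baseline_event_prob
  # unpaired drugs: E[rm^X] and P(X = 0)
  un <- drugs[!drugs$name %in% paired]
  e_factor <- prod(1 - un$exposure_prob + un$exposure_prob * un$risk_multiplier)
  p_zero <- prod(1 - un$exposure_prob)
  e_zero_factor <- p_zero  # rm^0 = 1 on the no-drug event
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      d1 <- drugs[drugs$name == pairs$drug1[i]]
      d2 <- drugs[drugs$name == pairs$drug2[i]]
      p1 <- d1$exposure_prob; p2 <- d2$exposure_prob
      r1 <- d1$risk_multiplier; r2 <- d2$risk_multiplier
      bst <- pairs$corx_boost[i]; im <- pairs$interaction_multiplier[i]
      p11 <- p1 * p2 + bst * (p1 * (1 - p2) + (1 - p1) * p2)
      p10 <- p1 * (1 - p2) * (1 - bst)
      p01 <- (1 - p1) * p2 * (1 - bst)
      p00 <- (1 - p1) * (1 - p2)
      e_factor <- e_factor * (p00 + p10 * r1 + p01 * r2 + p11 * r1 * r2 * im)
      p_zero <- p_zero * p00
      e_zero_factor <- e_zero_factor * p00
    }
  }
  e_uncond <- b * e_factor                  # E[p] over all draws
  e_zero <- b * e_zero_factor               # E[p * 1(no drugs)]
  (e_uncond - e_zero) / (1 - p_zero)
}

sample_cat <- function(n, dist) {
  sample(names(dist), n, replace = TRUE, prob = dist)
}

#' Generate a synthetic report collection
#'
#' Draws reports from a [synthetic_config()]: (1) per-drug exposures are
#' sampled independently, then for each designated pair with exactly one
#' member present the partner is added with probability `corx_boost`;
#' (2) the event probability is
#' `min(0.99, baseline * prod(risk multipliers of exposed drugs) *
#' prod(interaction multipliers of co-exposed pairs))` and the event is
#' sampled; case reports receive the target PT (plus sometimes a
#' background PT), non-cases a background PT; (3) one random exposed drug
#' is coded PS, the others C, and on case reports a co-exposed designated
#' pair is recoded I with probability `interacting_role_prob`;
#' (4) reporter type and demographics are sampled from the configured
#' categoricals. Draws with no exposed drug are discarded. The whole
#' stream is reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` when given.
#' @return a [report_collection()].
#' @export
generate_reports <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- seed %||% config$seed
  with_seed(seed, generate_reports_impl(config))
}

generate_reports_impl <- function(config) {
  n <- config$n_reports
  drugs <- config$drugs
  pairs <- config$pairs
  nd <- nrow(drugs)
  probs <- drugs$exposure_prob

  # (1) exposures: independent margins, then pairwise co-prescription boost
  expos <- matrix(runif(n * nd) < rep(probs, each = n), nrow = n, ncol = nd)
  i1 <- match(pairs$drug1, drugs$name)
  i2 <- match(pairs$drug2, drugs$name)
  for (k in seq_len(nrow(pairs))) {
    u <- runif(n)
    has1 <- expos[, i1[k]]; has2 <- expos[, i2[k]]
    hit <- u < pairs$corx_boost[k]
    expos[has1 & !has2 & hit, i2[k]] <- TRUE
    expos[!has1 & has2 & hit, i1[k]] <- TRUE
  }

  # (2) event probability and event
  logrel <- as.vector(expos %*% log(drugs$risk_multiplier))
  for (k in seq_len(nrow(pairs))) {
    co <- expos[, i1[k]] & expos[, i2[k]]
    logrel[co] <- logrel[co] + log(pairs$interaction_multiplier[k])
  }
  p_event <- pmin(0.99, config$baseline_event_prob * exp(logrel))
  event <- runif(n) < p_event

  # reactions: cases get the target PT (plus a background PT 40% of the
  # time); non-cases get one background PT, a second one 30% of the time
  u_extra <- runif(n)
  pt1 <- sample(config$pt_pool, n, replace = TRUE)
  pt2 <- sample(config$pt_pool, n, replace = TRUE)

  # (3) roles: one random exposed drug is PS (random priority argmax)
  prio <- matrix(runif(n * nd), nrow = n, ncol = nd)
  prio[!expos] <- -1
  ps_col <- max.col(prio, ties.method = "first")
  u_role <- if (nrow(pairs)) matrix(runif(n * nrow(pairs)), nrow = n) else NULL

  # (4) demographics
  reporter <- sample_cat(n, config$reporter_distribution)
  sex <- sample_cat(n, config$sex_distribution)
  band <- sample_cat(n, config$age_band_distribution)
  age <- rep(NA_real_, n)
  band_lo <- c("0-19" = 0, "20-39" = 20, "40-59" = 40, "60-79" = 60, "80+" = 80)
  band_hi <- c("0-19" = 19, "20-39" = 39, "40-59" = 59, "60-79" = 79, "80+" = 97)
  known <- band != "unknown"
  age[known] <- floor(runif(sum(known), band_lo[band[known]],
                            band_hi[band[known]] + 1))
  country <- sample_cat(n, config$country_distribution)
  outcome <- sample_cat(n, config$outcome_distribution)

  keep <- rowSums(expos) > 0L
  kid <- which(keep)
  report_id <- sprintf("R%07d", seq_len(n))

  # drug entry table with roles
  role <- matrix("", nrow = n, ncol = nd)
  role[expos] <- "C"
  ps_idx <- cbind(seq_len(n), ps_col)
  role[ps_idx[keep & expos[ps_idx], , drop = FALSE]] <- "PS"
  for (k in seq_len(nrow(pairs))) {
    mark <- expos[, i1[k]] & expos[, i2[k]] & event &
      (u_role[, k] < config$interacting_role_prob)
    role[mark, i1[k]] <- "I"
    role[mark, i2[k]] <- "I"
  }
  which_exp <- which(expos[kid, , drop = FALSE], arr.ind = TRUE)
  drug_tab <- data.table(
    report_id = report_id[kid[which_exp[, 1]]],
    drug_name = drugs$name[which_exp[, 2]],
    role_code = role[cbind(kid[which_exp[, 1]], which_exp[, 2])]
  )

  # reaction table
  ev_k <- event[kid]
  reac_list <- vector("list", 3L)
  reac_list[[1]] <- data.table(report_id = report_id[kid[ev_k]],
                               pt_code = config$target_pt)
  extra_case <- kid[ev_k & u_extra[kid] < 0.4]
  reac_list[[2]] <- data.table(report_id = report_id[extra_case],
                               pt_code = pt1[extra_case])
  noncase <- kid[!ev_k]
  second <- noncase[u_extra[noncase] < 0.3]
  reac_list[[3]] <- rbindlist(list(
    data.table(report_id = report_id[noncase], pt_code = pt1[noncase]),
    data.table(report_id = report_id[second], pt_code = pt2[second])
  ))
  reac_tab <- rbindlist(reac_list)

  demo_tab <- data.table(
    report_id = report_id[kid],
    reporter_type = reporter[kid],
    sex = sex[kid],
    age_years = age[kid],
    country = country[kid]
  )
  outc_tab <- data.table(report_id = report_id[kid], outcome = outcome[kid])

  report_collection(demo = demo_tab, drugs = drug_tab,
                    reactions = reac_tab, outcomes = outc_tab)
}

#' Compendium reference table matched to the benchmark configuration
#'
#' Emulates the Lexicomp/Drugs.com lookup for the planted ground truth of
#' [benchmark_default()]: three synergy pairs indexed by both sources, one
#' by Lexicomp only, one unindexed; all five no-synergy risk pairs and the
#' antagonistic plant pair indexed by both sources (they emulate
#' well-documented QT-drug combinations); one co-prescription pair indexed
#' by Drugs.com only.
#'
#' @param config a configuration from [benchmark_default()].
#' @return a reference `data.table` as returned by [load_reference()].
#' @export
benchmark_reference <- function(config = benchmark_default()) {
  p <- config$pairs
  both <- function(d1, d2, lex_sev, drc_sev) {
    data.table(drug1 = c(d1, d1), drug2 = c(d2, d2),
               source = c("lexicomp", "drugscom"),
               severity = c(lex_sev, drc_sev))
  }
  rows <- list()
  syn <- p[grepl("^syn", p$label)]
  for (i in 1:3) rows[[length(rows) + 1]] <-
    both(syn$drug1[i], syn$drug2[i], "D", "Major")
  rows[[length(rows) + 1]] <- data.table(drug1 = syn$drug1[4],
                                         drug2 = syn$drug2[4],
                                         source = "lexicomp", severity = "C")
  risk <- p[grepl("^risk", p$label)]
  for (i in seq_len(nrow(risk))) rows[[length(rows) + 1]] <-
    both(risk$drug1[i], risk$drug2[i], "D", "Major")
  plant <- p[p$label == "negctrl"]
  rows[[length(rows) + 1]] <- both(plant$drug1, plant$drug2, "X", "Major")
  corx <- p[grepl("^corx", p$label)]
  rows[[length(rows) + 1]] <- data.table(drug1 = corx$drug1[1],
                                         drug2 = corx$drug2[1],
                                         source = "drugscom",
                                         severity = "Moderate")
  load_reference(rbindlist(rows))
}

#' Drug-level risk annotations matched to the benchmark configuration
#'
#' @param config a configuration from [benchmark_default()].
#' @return an annotation `data.table` as returned by [load_annotations()]:
#'   risk-pair and plant drugs annotated `known`/`highest`, synergy-pair
#'   drugs `possible`/`moderate`.
#' @export
benchmark_annotations <- function(config = benchmark_default()) {
  p <- config$pairs
  risky <- c(p[grepl("^risk", p$label) | p$label == "negctrl", drug1],
             p[grepl("^risk", p$label) | p$label == "negctrl", drug2])
  syn <- c(p[grepl("^syn", p$label), drug1], p[grepl("^syn", p$label), drug2])
  load_annotations(data.table(
    drug = c(risky, syn),
    credible_meds = c(rep("known", length(risky)),
                      rep("possible", length(syn))),
    uptodate = c(rep("highest", length(risky)),
                 rep("moderate", length(syn)))
  ))
}

#' Write / read a synthetic configuration
#'
#' Round-trips a [synthetic_config()] through a YAML file representation.
#'
#' @param config a [synthetic_config()].
#' @param path YAML file path.
#' @return `read_config()` returns the reconstructed [synthetic_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$drugs <- as.data.frame(x$drugs)
  x$pairs <- as.data.frame(x$pairs)
  dist_to_list <- function(d) as.list(d)
  for (nm in c("reporter_distribution", "sex_distribution",
               "age_band_distribution", "country_distribution",
               "outcome_distribution")) {
    x[[nm]] <- dist_to_list(x[[nm]])
  }
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  to_vec <- function(l) unlist(l)
  synthetic_config(
    n_reports = x$n_reports,
    baseline_event_prob = x$baseline_event_prob,
    drugs = as.data.table(lapply(x$drugs, unlist)),
    pairs = if (length(x$pairs$drug1))
      as.data.table(lapply(x$pairs, unlist)) else NULL,
    reporter_distribution = to_vec(x$reporter_distribution),
    sex_distribution = to_vec(x$sex_distribution),
    age_band_distribution = to_vec(x$age_band_distribution),
    country_distribution = to_vec(x$country_distribution),
    outcome_distribution = to_vec(x$outcome_distribution),
    target_pt = x$target_pt,
    pt_pool = x$pt_pool,
    interacting_role_prob = x$interacting_role_prob,
    seed = x$seed
  )
}
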