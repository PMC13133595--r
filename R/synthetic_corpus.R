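## Seeded synthetic registry corpora with planted ground truth. The
## defaults encode the stated world being emulated: ~33% of studies using
## at least one named instrument, start years 2012-2021 with a rising
## logit trend (27.6% -> 36.2%), ~5.8 outcomes per study, Table-2-like
## covariate margins and the reported covariate odds ratios as generating
## effects.

SITE_VOCAB <- list(
  breast = c("breast cancer", "metastatic breast cancer",
             "breast carcinoma", "triple negative breast neoplasm",
             "early breast cancer"),
  digestive = c("colorectal cancer", "gastric cancer",
                "pancreatic adenocarcinoma", "colon carcinoma",
                "rectal cancer"),
  prostate = c("prostate cancer", "metastatic prostate carcinoma",
               "castration resistant prostate cancer"),
  lung = c("non small cell lung cancer", "lung adenocarcinoma",
           "small cell lung carcinoma", "lung cancer"),
  urogenital = c("bladder cancer", "renal cell carcinoma",
                 "kidney cancer", "urothelial carcinoma"),
  head_neck = c("head and neck squamous cell carcinoma",
                "oropharyngeal cancer", "laryngeal cancer"),
  hematopoietic = c("acute myeloid leukemia",
                    "chronic lymphocytic leukemia", "multiple myeloma",
                    "non hodgkin lymphoma"),
  brain = c("glioblastoma", "brain tumor", "glioma"),
  other = c("thyroid cancer", "melanoma of the skin",
            "soft tissue sarcoma", "neuroendocrine tumor"))

SITE_PROBS <- c(breast = 0.22, digestive = 0.20, prostate = 0.11,
                lung = 0.10, urogenital = 0.08, head_neck = 0.06,
                hematopoietic = 0.03, brain = 0.03, other = 0.17)

POS_PREFIXES <- c("Change in ", "Mean score on the ",
                  "Change from baseline in ", "Patient-completed ",
                  "Global health status measured with the ")
POS_SUFFIXES <- c(" score at week 12", " total score", " at 6 months",
                  " summary score", "")

NEG_TEMPLATES <- c(
  "Overall survival measured from randomization to death",
  "Progression-free survival at 12 months",
  "Objective response rate per RECIST 1.1",
  "Incidence of grade 3-4 adverse events",
  "Maximum tolerated dose of the combination",
  "Change in tumor volume on imaging",
  "Serum biomarker concentration at cycle 3",
  "Time to disease progression",
  "Duration of hospital stay in days",
  "Pharmacokinetic profile of the study drug")

TRAP_TEMPLATES <- list(
  uppercase_symptom = c("Severity of PAIN recorded daily by the clinician",
                        "FATIGUE graded by the treating physician"),
  ad_hoc = c("Symptom burden assessed with ad hoc study-specific items",
             "Response to ad hoc items developed for this trial"),
  clinician = c("Clinician-assessed performance status at each visit",
                "Physician-rated toxicity grading per protocol"))

## Default instrument mix: the published instrument-repartition
## proportions for the nine most frequent instruments.
default_instrument_mix <- function() {
  c(eortc_qlq_c30 = 33.2, fact_g = 15.2, eq_5d_5l = 11.5, hads = 9.1,
    cancer_related_qol = 8.6, nci_proq = 8.5, pro_ctcae = 6.1,
    c_vas = 5.5, ipss = 2.3)
}

default_covariate_effects <- function() {
  list("phase=phase2" = log(1.8), "phase=phase3" = log(3.6),
       "phase=phase4" = log(2.6), "allocation=randomized" = log(2.0),
       "primary_purpose=supportive_care" = log(4.1),
       "time_perspective=prospective" = log(3.2),
       "time_perspective=cross_sectional" = log(4.6),
       "observational_model=cohort" = log(1.6))
}

#' Build a synthetic corpus configuration
#'
#' @param n_studies Number of studies.
#' @param seed Mandatory integer seed; the corpus is a deterministic
#'   function of the config.
#' @param prevalence Target fraction of studies using at least one named
#'   instrument (default 0.33).
#' @param outcomes_per_study List `lambda`, `min`: truncated Poisson
#'   (default lambda 5, min 1, emulating ~5.8 outcomes/study).
#' @param instrument_mix Named non-negative weights over lexicon
#'   `instrument_id`s (default: the nine-instrument published mix).
#' @param variant_rates Rates of surface corruption for planted mentions:
#'   `acronym_only`, `hyphen_drop`, `fragment_multiword`, `typo`.
#' @param trap_rates Rates at which negative outcomes carry trap phrases
#'   (`uppercase_symptom`, `ad_hoc`, `clinician`) that must not count as
#'   named instruments.
#' @param covariate_effects Named list `"column=level" -> log-OR` entering
#'   the generating logistic model (defaults: the reported odds ratios).
#' @param year_range Integer start years (default 2012:2021).
#' @param trend_slope Per-year log-odds slope (default 0.044, the slope
#'   implied by 27.6% -> 36.2% over nine years).
#' @param prop_interventional Fraction of interventional studies
#'   (default 0.79).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_studies, seed,
                             prevalence = 0.33,
                             outcomes_per_study = list(lambda = 5, min = 1),
                             instrument_mix = default_instrument_mix(),
                             variant_rates = list(acronym_only = 0.3,
                                                  hyphen_drop = 0.1,
                                                  fragment_multiword = 0.05,
                                                  typo = 0.05),
                             trap_rates = list(uppercase_symptom = 0.05,
                                               ad_hoc = 0.05,
                                               clinician = 0.05),
                             covariate_effects = default_covariate_effects(),
                             year_range = 2012:2021,
                             trend_slope = 0.044,
                             prop_interventional = 0.79) {
  if (missing(seed)) stop("seed is mandatory")
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  if (any(instrument_mix < 0) || all(instrument_mix == 0)) {
    stop("instrument_mix weights must be non-negative and not all zero")
  }
  structure(list(n_studies = as.integer(n_studies), seed = as.integer(seed),
                 prevalence = prevalence,
                 outcomes_per_study = outcomes_per_study,
                 instrument_mix = instrument_mix,
                 variant_rates = variant_rates, trap_rates = trap_rates,
                 covariate_effects = covariate_effects,
                 year_range = year_range, trend_slope = trend_slope,
                 prop_interventional = prop_interventional),
            class = "synthetic_config")
}

sample_level <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

draw_covariates <- function(n, cfg) {
  study_type <- ifelse(stats::runif(n) < cfg$prop_interventional,
                       "interventional", "observational")
  phase <- sample_level(n, c(early_phase1 = 0.019, phase1 = 0.131,
                             phase1_2 = 0.079, phase2 = 0.270,
                             phase2_3 = 0.015, phase3 = 0.085,
                             phase4 = 0.023, missing = 0.378))
  model <- sample_level(n, c(parallel = 0.482, single_group = 0.445,
                             crossover = 0.019, factorial = 0.006,
                             sequential = 0.045, missing = 0.003))
  allocation <- ifelse(model %in% c("single_group", "sequential"),
                       "not_applicable",
                       ifelse(stats::runif(n) < 0.77, "randomized",
                              "nonrandomized"))
  purpose <- sample_level(n, c(treatment = 0.662, supportive_care = 0.106,
                               diagnostic = 0.081, prevention = 0.053,
                               other = 0.092, missing = 0.006))
  obs_model <- sample_level(n, c(cohort = 0.640, case_control = 0.104,
                                 case_only = 0.143, other = 0.101,
                                 missing = 0.012))
  time_persp <- sample_level(n, c(prospective = 0.723, retrospective = 0.162,
                                  cross_sectional = 0.070, other = 0.040,
                                  missing = 0.005))
  interventional <- study_type == "interventional"
  data.frame(
    study_type = study_type,
    phase = ifelse(interventional, phase, "missing"),
    allocation = ifelse(interventional, allocation, "missing"),
    intervention_model = ifelse(interventional, model, "missing"),
    primary_purpose = ifelse(interventional, purpose, "missing"),
    observational_model = ifelse(interventional, "missing", obs_model),
    time_perspective = ifelse(interventional, "missing", time_persp),
    site_label = sample_level(n, SITE_PROBS),
    year = sample(cfg$year_range, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

effect_eta <- function(cov, effects) {
  eta <- numeric(nrow(cov))
  for (key in names(effects)) {
    kv <- strsplit(key, "=", fixed = TRUE)[[1]]
    if (!kv[1] %in% names(cov)) stop("unknown effect column: ", kv[1])
    eta <- eta + effects[[key]] * (cov[[kv[1]]] == kv[2])
  }
  eta
}

corrupt_surface <- function(surface, variant) {
  if (variant == "hyphen_drop") {
    return(gsub("-", " ", surface, fixed = TRUE))
  }
  if (variant == "fragment_multiword") {
    return(sub(" ", ", ", surface, fixed = TRUE))  # punctuation wedge
  }
  if (variant == "typo") {
    chars <- strsplit(surface, "")[[1]]
    letters_ix <- which(grepl("[A-Za-z]", chars))
    if (length(letters_ix) >= 2L) {
      i <- letters_ix[sample(length(letters_ix) - 1L, 1L)]
      chars[c(i, i + 1L)] <- chars[c(i + 1L, i)]
    }
    return(paste0(chars, collapse = ""))
  }
  surface
}

#' Generate a synthetic registry corpus with ground truth
#'
#' Outcome texts are composed from templated clinical phrasing: positives
#' embed an instrument surface form (canonical name, acronym, or a
#' configured corruption) at a recorded character span; negatives
#' optionally embed trap phrases (uppercase symptom tokens, ad hoc item
#' phrasing, clinician-reported phrasing) that must *not* count as named
#' instruments under the labeling rule. Study covariates are drawn so the
#' generating logistic model (configured effects plus a calibrated
#' intercept and the year trend) holds exactly. Fully reproducible from
#' the seed.
#'
#' @param config A `synthetic_config`.
#' @param lexicon The instrument lexicon to plant from (default: the
#'   packaged fixture).
#' @return A list with `studies` (list of `study_record`) and
#'   `ground_truth` (list with `outcomes` and `studies` data.frames).
#' @export
generate_corpus <- function(config, lexicon = read_lexicon()) {
  stopifnot(inherits(config, "synthetic_config"))
  unknown <- setdiff(names(config$instrument_mix),
                     lexicon$entries$instrument_id)
  if (length(unknown) > 0L) {
    stop("instrument_mix references unknown instruments: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(config$seed)
  n <- config$n_studies
  cov <- draw_covariates(n, config)
  eta0 <- effect_eta(cov, config$covariate_effects) +
    config$trend_slope * (cov$year - mean(config$year_range))
  intercept <- if (n > 0L) {
    stats::uniroot(function(b0) mean(stats::plogis(b0 + eta0)) -
                     config$prevalence,
                   interval = c(-20, 20))$root
  } else 0
  uses <- if (n > 0L) {
    stats::rbinom(n, 1L, stats::plogis(intercept + eta0))
  } else integer(0)

  mix <- config$instrument_mix / sum(config$instrument_mix)
  entries <- lexicon$entries
  vr <- config$variant_rates
  tr <- config$trap_rates
  variant_names <- c("hyphen_drop", "fragment_multiword", "typo")
  variant_probs <- c(vr$hyphen_drop, vr$fragment_multiword, vr$typo)
  trap_names <- names(TRAP_TEMPLATES)
  trap_probs <- c(tr$uppercase_symptom, tr$ad_hoc, tr$clinician)

  studies <- vector("list", n)
  gt_out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- stats::rpois(1L, config$outcomes_per_study$lambda)
    while (k < config$outcomes_per_study$min) {  # truncation by rejection
      k <- stats::rpois(1L, config$outcomes_per_study$lambda)
    }
    pos <- logical(k)
    if (uses[i] == 1L) {
      pos <- stats::runif(k) < 0.5
      if (!any(pos)) pos[sample.int(k, 1L)] <- TRUE
    }
    text <- character(k)
    inst <- rep(NA_character_, k)
    span_start <- rep(NA_integer_, k)
    span_end <- rep(NA_integer_, k)
    trap <- rep(NA_character_, k)
    for (j in seq_len(k)) {
      if (pos[j]) {
        id <- sample(names(mix), 1L, prob = mix)
        e <- entries[entries$instrument_id == id, ]
        acronyms <- e$acronyms[[1]]
        surface <- if (length(acronyms) > 0L &&
                       stats::runif(1) < vr$acronym_only) {
          sample(acronyms, 1L)
        } else {
          e$canonical_name
        }
        u <- stats::runif(1)
        cum <- cumsum(variant_probs)
        variant <- if (u < cum[1]) variant_names[1] else
          if (u < cum[2]) variant_names[2] else
            if (u < cum[3]) variant_names[3] else "none"
        surface <- corrupt_surface(surface, variant)
        prefix <- sample(POS_PREFIXES, 1L)
        suffix <- sample(POS_SUFFIXES, 1L)
        text[j] <- paste0(prefix, surface, suffix)
        inst[j] <- id
        span_start[j] <- nchar(prefix) + 1L
        span_end[j] <- nchar(prefix) + nchar(surface) + 1L
      } else {
        u <- stats::runif(1)
        cum <- cumsum(trap_probs)
        which_trap <- if (u < cum[1]) trap_names[1] else
          if (u < cum[2]) trap_names[2] else
            if (u < cum[3]) trap_names[3] else NA_character_
        if (!is.na(which_trap)) {
          text[j] <- sample(TRAP_TEMPLATES[[which_trap]], 1L)
          trap[j] <- which_trap
        } else {
          text[j] <- sample(NEG_TEMPLATES, 1L)
        }
      }
    }
    study_id <- sprintf("SYN%08d", i)
    start_date <- as.Date(sprintf("%d-%02d-%02d", cov$year[i],
                                  sample.int(12L, 1L),
                                  sample.int(28L, 1L)))
    outcomes <- data.frame(outcome_index = seq_len(k), title = "",
                           description = text,
                           rank = c("primary",
                                    rep("secondary", k - 1L)),
                           stringsAsFactors = FALSE)
    conditions <- sample(SITE_VOCAB[[cov$site_label[i]]], 1L)
    studies[[i]] <- structure(
      list(study_id = study_id, start_date = start_date,
           study_type = cov$study_type[i], phase = cov$phase[i],
           allocation = cov$allocation[i],
           intervention_model = cov$intervention_model[i],
           primary_purpose = cov$primary_purpose[i],
           observational_model = cov$observational_model[i],
           time_perspective = cov$time_perspective[i],
           conditions = conditions, outcomes = outcomes),
      class = "study_record")
    gt_out[[i]] <- data.frame(
      study_id = study_id, outcome_index = seq_len(k),
      contains_named_instrument = pos, instrument_id = inst,
      span_start = span_start, span_end = span_end, trap = trap,
      stringsAsFactors = FALSE)
  }
  gt_studies <- cbind(data.frame(
    study_id = vapply(studies, function(s) s$study_id, character(1)),
    uses_prompem = uses, stringsAsFactors = FALSE), cov)
  if (n == 0L) {
    gt_studies <- data.frame(study_id = character(0),
                             uses_prompem = integer(0))
  }
  list(studies = studies,
       ground_truth = list(
         outcomes = if (n > 0L) do.call(rbind, gt_out) else
           data.frame(study_id = character(0), outcome_index = integer(0),
                      contains_named_instrument = logical(0),
                      instrument_id = character(0),
                      span_start = integer(0), span_end = integer(0),
                      trap = character(0), stringsAsFactors = FALSE),
         studies = gt_studies,
         intercept = intercept, config = config))
}

#' Summarize a generated corpus from its ground truth
#'
#' Exact summaries used as oracles by downstream tests: study-level
#' prevalence, planted instrument frequencies (per-study, deduplicated),
#' trap counts, and per-year prevalence.
#'
#' @param ground_truth The `ground_truth` element of [generate_corpus()].
#' @return A list with `prevalence`, `instrument_frequencies`,
#'   `trap_counts`, `per_year`.
#' @export
corpus_report <- function(ground_truth) {
  st <- ground_truth$studies
  out <- ground_truth$outcomes
  prevalence <- if (nrow(st) > 0L) mean(st$uses_prompem) else 0
  planted <- out[!is.na(out$instrument_id), , drop = FALSE]
  freq <- if (nrow(planted) > 0L) {
    pairs <- unique(planted[, c("study_id", "instrument_id")])
    tab <- sort(table(pairs$instrument_id), decreasing = TRUE)
    data.frame(instrument_id = names(tab), n_studies = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(instrument_id = character(0), n_studies = integer(0),
               stringsAsFactors = FALSE)
  }
  trap_counts <- table(out$trap[!is.na(out$trap)])
  per_year <- if (nrow(st) > 0L) {
    years <- sort(unique(st$year))
    data.frame(year = years,
               n = vapply(years, function(y) sum(st$year == y), integer(1)),
               prevalence = vapply(years, function(y) {
                 mean(st$uses_prompem[st$year == y])
               }, numeric(1)))
  } else {
    data.frame(year = integer(0), n = integer(0), prevalence = numeric(0))
  }
  list(prevalence = prevalence, instrument_frequencies = freq,
       trap_counts = trap_counts, per_year = per_year)
}
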