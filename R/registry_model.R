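## Registry study records: parsing from the public-API JSON dialect,
## eligibility filtering, and explosion into analyzable outcome rows.

PHASE_LEVELS <- c("early_phase1", "phase1", "phase1_2", "phase2", "phase2_3",
                  "phase3", "phase4", "missing")
ALLOCATION_LEVELS <- c("randomized", "nonrandomized", "not_applicable", "missing")
MODEL_LEVELS <- c("parallel", "single_group", "crossover", "factorial",
                  "sequential", "missing")
PURPOSE_LEVELS <- c("treatment", "supportive_care", "diagnostic", "prevention",
                    "other", "missing")
OBS_MODEL_LEVELS <- c("cohort", "case_control", "case_only", "other", "missing")
TIME_LEVELS <- c("prospective", "retrospective", "cross_sectional", "other",
                 "missing")
RANK_LEVELS <- c("primary", "secondary", "other")

map_enum <- function(value, mapping, other = NULL) {
  if (is.null(value) || length(value) == 0L || is.na(value) || !nzchar(value)) {
    return("missing")
  }
  key <- toupper(gsub("[ -]", "_", trimws(value)))
  if (key %in% names(mapping)) return(unname(mapping[[key]]))
  if (!is.null(other)) return(other)
  "missing"
}

map_phase <- function(phases) {
  if (is.null(phases) || length(phases) == 0L) return("missing")
  phases <- toupper(unlist(phases, use.names = FALSE))
  phases <- phases[nzchar(phases)]
  if (length(phases) == 0L || all(phases == "NA")) return("missing")
  has <- function(p) any(phases == p)
  if (has("EARLY_PHASE1")) return("early_phase1")
  if (has("PHASE1") && has("PHASE2")) return("phase1_2")
  if (has("PHASE2") && has("PHASE3")) return("phase2_3")
  if (has("PHASE1")) return("phase1")
  if (has("PHASE2")) return("phase2")
  if (has("PHASE3")) return("phase3")
  if (has("PHASE4")) return("phase4")
  "missing"
}

#' Parse one registry study record
#'
#' Maps a single study object in the registry API JSON dialect (as returned
#' by [read_registry_records()]) onto a typed `study_record`. Unrecognized
#' or absent enum values become the explicit level `"missing"`, never `NA`;
#' conditions and outcomes are preserved in input order. Fields that only
#' apply to the other study type are forced to `"missing"`.
#'
#' @param raw A list: one study object of the registry dialect.
#' @return A `study_record` object.
#' @export
parse_study_record <- function(raw) {
  ps <- raw$protocolSection
  if (is.null(ps)) ps <- raw
  study_id <- ps$identificationModule$nctId
  if (is.null(study_id) || !nzchar(study_id)) {
    stop("malformed record: missing field 'identificationModule$nctId'")
  }
  date_str <- ps$statusModule$startDateStruct$date
  start_date <- if (is.null(date_str) || !nzchar(date_str)) {
    as.Date(NA)
  } else {
    if (grepl("^[0-9]{4}-[0-9]{2}$", date_str)) date_str <- paste0(date_str, "-01")
    as.Date(date_str)
  }
  dm <- ps$designModule
  di <- dm$designInfo
  study_type <- map_enum(dm$studyType,
                         c(INTERVENTIONAL = "interventional",
                           OBSERVATIONAL = "observational"))
  interventional <- identical(study_type, "interventional")
  observational <- identical(study_type, "observational")
  phase <- if (interventional) map_phase(dm$phases) else "missing"
  allocation <- if (interventional) {
    map_enum(di$allocation,
             c(RANDOMIZED = "randomized", NON_RANDOMIZED = "nonrandomized",
               NONRANDOMIZED = "nonrandomized", NA_ = "not_applicable",
               "NA" = "not_applicable"))
  } else "missing"
  intervention_model <- if (interventional) {
    map_enum(di$interventionModel,
             c(PARALLEL = "parallel", SINGLE_GROUP = "single_group",
               CROSSOVER = "crossover", FACTORIAL = "factorial",
               SEQUENTIAL = "sequential"))
  } else "missing"
  primary_purpose <- if (interventional) {
    map_enum(di$primaryPurpose,
             c(TREATMENT = "treatment", SUPPORTIVE_CARE = "supportive_care",
               DIAGNOSTIC = "diagnostic", PREVENTION = "prevention",
               OTHER = "other"),
             other = "other")
  } else "missing"
  observational_model <- if (observational) {
    map_enum(di$observationalModel,
             c(COHORT = "cohort", CASE_CONTROL = "case_control",
               CASE_ONLY = "case_only", OTHER = "other"),
             other = "other")
  } else "missing"
  time_perspective <- if (observational) {
    map_enum(di$timePerspective,
             c(PROSPECTIVE = "prospective", RETROSPECTIVE = "retrospective",
               CROSS_SECTIONAL = "cross_sectional", OTHER = "other"),
             other = "other")
  } else "missing"

  conditions <- as.character(unlist(ps$conditionsModule$conditions,
                                    use.names = FALSE))
  om <- ps$outcomesModule
  grab <- function(lst, rank) {
    if (is.null(lst) || length(lst) == 0L) return(NULL)
    data.frame(
      title = vapply(lst, function(o) o$measure %||% "", character(1)),
      description = vapply(lst, function(o) o$description %||% "", character(1)),
      rank = rank, stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, c(list(grab(om$primaryOutcomes, "primary"),
                                    grab(om$secondaryOutcomes, "secondary"),
                                    grab(om$otherOutcomes, "other"))))
  if (is.null(outcomes)) {
    outcomes <- data.frame(title = character(0), description = character(0),
                           rank = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(outcomes) > 0L) outcomes$outcome_index <- seq_len(nrow(outcomes))
  else outcomes$outcome_index <- integer(0)
  outcomes <- outcomes[, c("outcome_index", "title", "description", "rank")]

  structure(list(study_id = study_id, start_date = start_date,
                 study_type = study_type, phase = phase,
                 allocation = allocation,
                 intervention_model = intervention_model,
                 primary_purpose = primary_purpose,
                 observational_model = observational_model,
                 time_perspective = time_perspective,
                 conditions = conditions, outcomes = outcomes),
            class = "study_record")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a

#' Serialize a study record back to the registry JSON dialect
#'
#' Inverse of [parse_study_record()] up to enum spelling: a serialized and
#' re-parsed record is field-identical.
#'
#' @param record A `study_record`.
#' @return A nested list following the registry dialect.
#' @export
serialize_study_record <- function(record) {
  stopifnot(inherits(record, "study_record"))
  unmap <- function(x, mapping) {
    if (identical(x, "missing")) NULL else unname(mapping[[x]])
  }
  interventional <- identical(record$study_type, "interventional")
  design_info <- list()
  if (interventional) {
    design_info$allocation <- unmap(record$allocation,
      list(randomized = "RANDOMIZED", nonrandomized = "NON_RANDOMIZED",
           not_applicable = "NA"))
    design_info$interventionModel <- unmap(record$intervention_model,
      list(parallel = "PARALLEL", single_group = "SINGLE_GROUP",
           crossover = "CROSSOVER", factorial = "FACTORIAL",
           sequential = "SEQUENTIAL"))
    design_info$primaryPurpose <- unmap(record$primary_purpose,
      list(treatment = "TREATMENT", supportive_care = "SUPPORTIVE_CARE",
           diagnostic = "DIAGNOSTIC", prevention = "PREVENTION",
           other = "OTHER"))
  } else {
    design_info$observationalModel <- unmap(record$observational_model,
      list(cohort = "COHORT", case_control = "CASE_CONTROL",
           case_only = "CASE_ONLY", other = "OTHER"))
    design_info$timePerspective <- unmap(record$time_perspective,
      list(prospective = "PROSPECTIVE", retrospective = "RETROSPECTIVE",
           cross_sectional = "CROSS_SECTIONAL", other = "OTHER"))
  }
  phases <- unmap(record$phase,
    list(early_phase1 = list("EARLY_PHASE1"), phase1 = list("PHASE1"),
         phase1_2 = list("PHASE1", "PHASE2"), phase2 = list("PHASE2"),
         phase2_3 = list("PHASE2", "PHASE3"), phase3 = list("PHASE3"),
         phase4 = list("PHASE4")))
  outcome_list <- function(rank) {
    sub <- record$outcomes[record$outcomes$rank == rank, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    lapply(seq_len(nrow(sub)), function(i) {
      list(measure = sub$title[i], description = sub$description[i])
    })
  }
  design_module <- list(
    studyType = if (interventional) "INTERVENTIONAL" else "OBSERVATIONAL")
  if (!is.null(phases)) design_module$phases <- phases
  design_info <- design_info[!vapply(design_info, is.null, logical(1))]
  if (length(design_info) > 0L) design_module$designInfo <- design_info
  out_mod <- list(primaryOutcomes = outcome_list("primary"),
                  secondaryOutcomes = outcome_list("secondary"),
                  otherOutcomes = outcome_list("other"))
  out_mod <- out_mod[!vapply(out_mod, is.null, logical(1))]
  list(protocolSection = list(
    identificationModule = list(nctId = record$study_id),
    statusModule = list(startDateStruct = list(
      date = if (is.na(record$start_date)) NULL else format(record$start_date))),
    designModule = design_module,
    conditionsModule = list(conditions = as.list(record$conditions)),
    outcomesModule = out_mod))
}

#' Read registry study records from a JSON or JSON-lines file
#'
#' Accepts either a JSON array of study objects or a JSON-lines file with
#' one study object per line.
#'
#' @param path File path.
#' @return A list of parsed `study_record` objects.
#' @export
read_registry_records <- function(path) {
  txt <- readLines(path, warn = FALSE, encoding = "UTF-8")
  joined <- trimws(paste(txt, collapse = "\n"))
  raws <- if (startsWith(joined, "[")) {
    jsonlite::fromJSON(joined, simplifyVector = FALSE)
  } else {
    lapply(txt[nzchar(trimws(txt))], jsonlite::fromJSON,
           simplifyVector = FALSE)
  }
  lapply(raws, parse_study_record)
}

#' Write study records as registry-dialect JSON lines
#'
#' @param studies List of `study_record` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry_jsonl <- function(studies, path) {
  lines <- vapply(studies, function(s) {
    jsonlite::toJSON(serialize_study_record(s), auto_unbox = TRUE,
                     null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Apply the eligibility filters
#'
#' Removes studies whose start date lies outside the half-open window
#' `[start, end)`, studies with no outcomes, and studies whose outcomes all
#' lack descriptions; within retained studies, individual outcomes with an
#' empty description are dropped. Conservation holds: the input count
#' equals the retained count plus the sum of the exclusion log.
#'
#' @param studies List of `study_record` objects.
#' @param window Length-2 `Date` vector (default 2012-01-01 to 2022-01-01).
#'   A study starting exactly on the end date is excluded.
#' @return A list with `eligible` (filtered records) and `exclusion_log`
#'   (named integer counts: `out_of_window`, `no_outcomes`,
#'   `no_outcome_description`).
#' @export
filter_eligible <- function(studies,
                            window = as.Date(c("2012-01-01", "2022-01-01"))) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[1] < window[2])
  log <- c(out_of_window = 0L, no_outcomes = 0L, no_outcome_description = 0L)
  eligible <- list()
  for (s in studies) {
    if (is.na(s$start_date) || s$start_date < window[1] ||
        s$start_date >= window[2]) {
      log["out_of_window"] <- log["out_of_window"] + 1L
      next
    }
    if (nrow(s$outcomes) == 0L) {
      log["no_outcomes"] <- log["no_outcomes"] + 1L
      next
    }
    keep <- nzchar(trimws(s$outcomes$description))
    if (!any(keep)) {
      log["no_outcome_description"] <- log["no_outcome_description"] + 1L
      next
    }
    s$outcomes <- s$outcomes[keep, , drop = FALSE]
    eligible[[length(eligible) + 1L]] <- s
  }
  list(eligible = eligible, exclusion_log = log)
}

#' Explode studies into a flat outcome table
#'
#' One row per outcome with the analysis text unit: title and description
#' concatenated with `". "` (matching and classification operate on this
#' combined text).
#'
#' @param studies List of `study_record` objects.
#' @return A data.frame with columns `study_id`, `outcome_index`, `rank`,
#'   `title`, `description`, `text`.
#' @export
outcomes_table <- function(studies) {
  rows <- lapply(studies, function(s) {
    o <- s$outcomes
    if (nrow(o) == 0L) return(NULL)
    data.frame(study_id = s$study_id, outcome_index = o$outcome_index,
               rank = o$rank, title = o$title, description = o$description,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(study_id = character(0), outcome_index = integer(0),
                      rank = character(0), title = character(0),
                      description = character(0), stringsAsFactors = FALSE)
  }
  title <- trimws(out$title)
  desc <- trimws(out$description)
  sep <- ifelse(nzchar(title) & nzchar(desc), ". ", "")
  out$text <- paste0(title, sep, desc)
  out
}

#' Write / read the flat outcome TSV
#'
#' @param outcomes A data.frame from [outcomes_table()].
#' @param path File path.
#' @return `path` (writer) or the outcome data.frame (reader).
#' @export
write_outcomes_tsv <- function(outcomes, path) {
  utils::write.table(outcomes, path, sep = "\t", quote = TRUE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_outcomes_tsv
#' @export
read_outcomes_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Condition-keyword oncology predicate
#'
#' Domain filtering is delegated to the caller; this helper flags a study
#' as oncology-related when any condition string contains one of the
#' keywords (case-insensitive).
#'
#' @param record A `study_record`.
#' @param keywords Character vector of lowercase keywords.
#' @return Logical scalar.
#' @export
is_oncology_study <- function(record,
                              keywords = c("cancer", "carcinoma", "tumor",
                                           "tumour", "neoplasm", "leukemia",
                                           "lymphoma", "melanoma", "sarcoma",
                                           "myeloma", "oncolog")) {
  conds <- tolower(record$conditions)
  any(vapply(keywords, function(k) any(grepl(k, conds, fixed = TRUE)),
             logical(1)))
}
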