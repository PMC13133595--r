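## The expert-style detector: search outcome texts for instrument surface
## forms (canonical names, acronyms) and the fixed generic-term lists.

## Compile every surface form into a word-boundary regex over normalized
## text. Hyphens inside a form are optional ("qlq-c30" also matches
## "qlq c30" and "qlqc30"); internal spaces tolerate a hyphen instead.
compile_surface_patterns <- function(lexicon = NULL, terms = NULL) {
  forms <- lexicon_surface_forms(lexicon, terms)
  if (is.null(forms) || nrow(forms) == 0L) {
    stop("configuration error: empty lexicon and empty generic-term list")
  }
  norm_surface <- vapply(forms$surface,
                         function(s) normalize_text(s)$text, character(1))
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", norm_surface)
  ## placeholders keep the two substitutions from interfering
  body <- gsub("-", "\x01", esc, fixed = TRUE)
  body <- gsub(" ", "\x02", body, fixed = TRUE)
  body <- gsub("\x01", "[- ]?", body, fixed = TRUE)
  body <- gsub("\x02", "[ -]", body, fixed = TRUE)
  forms$pattern <- paste0("(?<![a-z0-9])(?:", body, ")(?![a-z0-9])")
  forms$norm_surface <- norm_surface
  ## short acronyms additionally require casing evidence in the original
  forms$needs_case <- forms$source == "instrument_acronym" &
    nchar(gsub("[^a-zA-Z0-9]", "", forms$surface)) <= 4L
  forms
}

acronym_case_ok <- function(original) {
  grepl("[0-9]", original) ||
    (grepl("[A-Za-z]", original) && identical(original, toupper(original)))
}

#' Match one outcome text against lexicon and generic terms
#'
#' Returns whether any instrument canonical name, acronym, or generic term
#' occurs in the normalized text at word boundaries, together with every
#' hit's source, matched text and `[start, end)` span in the *original*
#' string. Matching is case-insensitive; acronyms of four or fewer
#' characters additionally require the original text to be uppercase or to
#' carry digits, so lowercase prose words that collide with an acronym
#' ("pain", "fact") do not fire. Overlapping hits are deduplicated keeping
#' the longest span, with instrument hits preferred over generic terms.
#'
#' @param text The outcome text (title + description unit).
#' @param lexicon An `instrument_lexicon` (or `NULL`).
#' @param terms A `generic_terms` list (or `NULL`).
#' @param outcome_key Optional `c(study_id, outcome_index)` identifier.
#' @param patterns Precompiled pattern table (internal; lets
#'   [flag_corpus()] compile once).
#' @return A list of class `match_result` with `outcome_key`, `matched`,
#'   and `hits` (data.frame: source, matched_text, start, end, id).
#' @export
match_outcome <- function(text, lexicon = NULL, terms = NULL,
                          outcome_key = NULL, patterns = NULL) {
  if (is.null(patterns)) patterns <- compile_surface_patterns(lexicon, terms)
  norm <- normalize_text(text)
  hits <- list()
  if (nzchar(norm$text)) {
    for (i in seq_len(nrow(patterns))) {
      m <- gregexpr(patterns$pattern[i], norm$text, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (j in seq_along(m)) {
        s <- as.integer(m[j])
        e <- s + attr(m, "match.length")[j]
        span <- denormalize_span(norm, c(s, e))
        original <- substring(text, span[1], span[2] - 1L)
        if (patterns$needs_case[i] && !acronym_case_ok(original)) next
        hits[[length(hits) + 1L]] <- data.frame(
          source = patterns$source[i], matched_text = original,
          start = span[1], end = span[2], id = patterns$id[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(source = character(0), matched_text = character(0),
               start = integer(0), end = integer(0), id = character(0),
               stringsAsFactors = FALSE)
  hits <- dedupe_hits(hits)
  structure(list(outcome_key = outcome_key,
                 matched = nrow(hits) > 0L, hits = hits),
            class = "match_result")
}

## Keep a non-overlapping hit set: longest span first, instrument sources
## before generic terms at equal length, then leftmost.
dedupe_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  priority <- ifelse(hits$source == "generic_term", 2L, 1L)
  ord <- order(-(hits$end - hits$start), priority, hits$start)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    overlaps <- keep & (hits$start < hits$end[i]) & (hits$end > hits$start[i])
    if (!any(overlaps)) keep[i] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag a whole outcome corpus
#'
#' Applies [match_outcome()] to every row of an outcome table and returns
#' per-outcome results plus summary counts. Deterministic.
#'
#' @param outcomes Data.frame with `study_id`, `outcome_index`, `text`
#'   (see [outcomes_table()]).
#' @param lexicon An `instrument_lexicon`.
#' @param terms A `generic_terms` list.
#' @return A list with `results` (list of `match_result`), `flags`
#'   (data.frame `study_id`, `outcome_index`, `matched`), and `summary`
#'   (named counts `matched`, `unmatched`).
#' @export
flag_corpus <- function(outcomes, lexicon, terms = generic_terms()) {
  patterns <- compile_surface_patterns(lexicon, terms)
  results <- lapply(seq_len(nrow(outcomes)), function(i) {
    match_outcome(outcomes$text[i], patterns = patterns,
                  outcome_key = c(outcomes$study_id[i],
                                  outcomes$outcome_index[i]))
  })
  matched <- vapply(results, function(r) r$matched, logical(1))
  flags <- data.frame(study_id = outcomes$study_id,
                      outcome_index = outcomes$outcome_index,
                      matched = matched, stringsAsFactors = FALSE)
  list(results = results, flags = flags,
       summary = c(matched = sum(matched), unmatched = sum(!matched)))
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result:", if (x$matched) "MATCHED" else "no match", "\n")
  if (nrow(x$hits) > 0L) print(x$hits)
  invisible(x)
}
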