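## Which instrument does an outcome name? BIO span annotation, a
## rule-assisted mention extractor, trigram-cosine normalization to the
## canonical lexicon, and study-level frequency tables.

#' Convert character spans to a BIO tag sequence
#'
#' Tokens covered by a span start with `B`, continuations get `I`, all
#' other tokens `O`, under the module tokenizer ([tokenize_spans()]:
#' whitespace with punctuation split off, internal hyphens kept).
#'
#' @param text The text.
#' @param spans Data.frame (or list) of non-overlapping half-open spans
#'   with `start` and `end` columns.
#' @return A list of class `bio_sequence` with `tokens`, `tags`, `starts`,
#'   `ends`.
#' @export
spans_to_bio <- function(text, spans) {
  toks <- tokenize_spans(text)
  spans <- as.data.frame(spans)
  tags <- rep("O", nrow(toks))
  if (nrow(spans) > 0L) {
    spans <- spans[order(spans$start), , drop = FALSE]
    if (any(spans$end > nchar(text) + 1L) || any(spans$start < 1L)) {
      stop("span lies outside the text")
    }
    if (nrow(spans) > 1L &&
        any(spans$start[-1] < spans$end[-nrow(spans)])) {
      stop("overlapping spans are not allowed")
    }
    for (k in seq_len(nrow(spans))) {
      covered <- which(toks$start < spans$end[k] & toks$end > spans$start[k])
      if (length(covered) == 0L) next
      tags[covered[1]] <- "B"
      if (length(covered) > 1L) tags[covered[-1]] <- "I"
    }
  }
  structure(list(tokens = toks$token, tags = tags,
                 starts = toks$start, ends = toks$end),
            class = "bio_sequence")
}

#' Recover character spans from a BIO sequence
#'
#' Inverse of [spans_to_bio()] for spans aligned to token boundaries.
#'
#' @param bio A `bio_sequence`.
#' @return Data.frame with `start`, `end` columns (half-open).
#' @export
bio_to_spans <- function(bio) {
  tags <- bio$tags
  if (length(tags) > 0L) {
    prev <- c("O", tags[-length(tags)])
    if (any(tags == "I" & !(prev %in% c("B", "I")))) {
      stop("invalid BIO sequence: I without preceding B or I")
    }
  }
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_along(tags)) {
    if (tags[i] == "B") {
      starts <- c(starts, bio$starts[i])
      ends <- c(ends, bio$ends[i])
    } else if (tags[i] == "I") {
      ends[length(ends)] <- bio$ends[i]
    }
  }
  data.frame(start = starts, end = ends)
}

## Heuristic instrument-like candidates in the original text:
## (1) acronym-shaped tokens (>=2 capitals, or capitals mixed with digits
##     and hyphens), (2) Title-Case runs ending in an instrument head noun.
HEAD_NOUNS <- c("Scale", "Questionnaire", "Survey", "Index", "Inventory",
                "Score", "Module", "Measure", "Test", "System", "Composite")

heuristic_candidates <- function(text) {
  toks <- tokenize_spans(text)
  out <- list()
  acro <- grepl("^(?:[A-Z]{2,}[0-9]*|[A-Z][A-Za-z]*[0-9][A-Za-z0-9]*)(?:-[A-Za-z0-9&]+)*$",
                toks$token)
  for (i in which(acro)) {
    out[[length(out) + 1L]] <- c(toks$start[i], toks$end[i])
  }
  title <- grepl("^[A-Z][a-z]+$|^[A-Z][a-z]+-[A-Za-z]+$", toks$token) |
    grepl("^[0-9]+$", toks$token)
  run_start <- NULL
  for (i in seq_len(nrow(toks))) {
    if (title[i]) {
      if (is.null(run_start)) run_start <- i
      if (toks$token[i] %in% HEAD_NOUNS && !is.null(run_start) &&
          i > run_start) {
        out[[length(out) + 1L]] <- c(toks$start[run_start], toks$end[i])
      }
    } else {
      run_start <- NULL
    }
  }
  out
}

#' Extract candidate instrument mentions from a text
#'
#' The default rule-assisted extractor combines lexicon-seeded span
#' finding (canonical names and acronyms of the supplied lexicon, via the
#' same matching rules as the expert-style detector) with instrument-like
#' pattern heuristics, then merges adjacent candidates separated by at
#' most `merge_gap` tokens — the countermeasure to multiword names being
#' fragmented into pieces like "Short Form" + "Health Survey". Any trained
#' tagger returning `{start, end}` spans can be plugged in via
#' `extractor`.
#'
#' @param text The outcome text.
#' @param lexicon An `instrument_lexicon` used to seed candidate spans.
#' @param extractor Optional function `function(text) data.frame(start,
#'   end)` replacing the built-in rules.
#' @param merge_gap Maximum number of tokens between mentions that are
#'   merged into one candidate (default 2).
#' @return Data.frame of unnormalized mentions: `surface_text`, `start`,
#'   `end`.
#' @export
extract_mentions <- function(text, lexicon = NULL, extractor = NULL,
                             merge_gap = 2L) {
  seeded <- list()
  heur <- list()
  if (!is.null(extractor)) {
    ex <- as.data.frame(extractor(text))
    heur <- lapply(seq_len(nrow(ex)), function(i) c(ex$start[i], ex$end[i]))
  } else {
    if (!is.null(lexicon)) {
      patterns <- compile_surface_patterns(lexicon, NULL)
      mr <- match_outcome(text, patterns = patterns)
      seeded <- lapply(seq_len(nrow(mr$hits)),
                       function(i) c(mr$hits$start[i], mr$hits$end[i]))
    }
    heur <- heuristic_candidates(text)
  }
  ## a lexicon-seeded span is authoritative: heuristic candidates that
  ## overlap one are dropped rather than merged into it
  if (length(seeded) > 0L && length(heur) > 0L) {
    heur <- Filter(function(h) {
      !any(vapply(seeded, function(s) h[1] < s[2] && h[2] > s[1],
                  logical(1)))
    }, heur)
  }
  if (length(seeded) + length(heur) == 0L) {
    return(data.frame(surface_text = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  toks <- tokenize_spans(text)
  merged <- list()
  if (length(heur) > 0L) {
    m <- unique(do.call(rbind, heur))
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    ## collapse overlaps, then merge near-adjacent heuristic fragments
    merged <- list(m[1, ])
    for (i in seq_len(nrow(m))[-1]) {
      last <- merged[[length(merged)]]
      gap_tokens <- sum(toks$start >= last[2] & toks$end <= m[i, 1])
      if (m[i, 1] <= last[2] || gap_tokens <= merge_gap) {
        merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
      } else {
        merged[[length(merged) + 1L]] <- m[i, ]
      }
    }
  }
  res <- unique(do.call(rbind, c(seeded, merged)))
  res <- res[order(res[, 1], res[, 2]), , drop = FALSE]
  data.frame(surface_text = substring(text, res[, 1], res[, 2] - 1L),
             start = res[, 1], end = res[, 2], stringsAsFactors = FALSE)
}

#' Normalize a mention against the canonical lexicon
#'
#' Similarity is the maximum character-trigram cosine (on folded text, so
#' case / hyphen / whitespace variants are equivalent) over all lexicon
#' surface forms (canonical names and acronyms). The argmax instrument is
#' assigned iff the similarity reaches `threshold`; ties break to the
#' lexicographically smallest `instrument_id`.
#'
#' @param mention One row of [extract_mentions()] output (or a list with
#'   `surface_text`, `start`, `end`).
#' @param lexicon An `instrument_lexicon`.
#' @param threshold Assignment threshold in `(0, 1]` (default 0.85, chosen
#'   so spacing/hyphen variants pass and unrelated acronyms fail on the
#'   fixture lexicon).
#' @return The mention as a one-row data.frame with added
#'   `normalized_instrument_id` (`NA` when unassigned) and `similarity`.
#' @export
normalize_mention <- function(mention, lexicon, threshold = 0.85) {
  if (is.null(lexicon) || nrow(lexicon$entries) == 0L) {
    stop("empty lexicon")
  }
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  forms <- lexicon_surface_forms(lexicon, NULL)
  sims <- vapply(forms$surface, trigram_cosine, numeric(1),
                 a = mention$surface_text)
  best <- max(sims)
  assigned <- NA_character_
  if (best >= threshold) {
    ids <- forms$id[sims == best]
    assigned <- sort(ids)[1]
  }
  data.frame(surface_text = mention$surface_text, start = mention$start,
             end = mention$end, normalized_instrument_id = assigned,
             similarity = best, stringsAsFactors = FALSE)
}

#' Extract and normalize mentions over a whole corpus
#'
#' @param outcomes Outcome table (`study_id`, `outcome_index`, `text`).
#' @param lexicon An `instrument_lexicon`.
#' @param threshold Passed to [normalize_mention()].
#' @param ... Passed to [extract_mentions()].
#' @return Data.frame of normalized mentions with outcome keys.
#' @export
corpus_mentions <- function(outcomes, lexicon, threshold = 0.85, ...) {
  rows <- lapply(seq_len(nrow(outcomes)), function(i) {
    m <- extract_mentions(outcomes$text[i], lexicon, ...)
    if (nrow(m) == 0L) return(NULL)
    norm <- do.call(rbind, lapply(seq_len(nrow(m)), function(j) {
      normalize_mention(m[j, ], lexicon, threshold)
    }))
    cbind(data.frame(study_id = outcomes$study_id[i],
                     outcome_index = outcomes$outcome_index[i],
                     stringsAsFactors = FALSE), norm)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(study_id = character(0), outcome_index = integer(0),
                      surface_text = character(0), start = integer(0),
                      end = integer(0),
                      normalized_instrument_id = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  }
  out
}

#' Study-level instrument frequency table
#'
#' Counts each instrument once per study; proportions are over the set of
#' studies with at least one assigned instrument (the published
#' instrument-repartition convention).
#'
#' @param mentions Normalized mentions (see [corpus_mentions()]).
#' @return Data.frame `instrument_id`, `n_studies`, `proportion`, sorted
#'   by decreasing count.
#' @export
instrument_frequencies <- function(mentions) {
  assigned <- mentions[!is.na(mentions$normalized_instrument_id), ,
                       drop = FALSE]
  if (nrow(assigned) == 0L) {
    return(data.frame(instrument_id = character(0), n_studies = integer(0),
                      proportion = numeric(0), stringsAsFactors = FALSE))
  }
  pairs <- unique(assigned[, c("study_id", "normalized_instrument_id")])
  n_base <- length(unique(pairs$study_id))
  tab <- sort(table(pairs$normalized_instrument_id), decreasing = TRUE)
  data.frame(instrument_id = names(tab), n_studies = as.integer(tab),
             proportion = as.numeric(tab) / n_base,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write mentions as JSON-lines span annotations
#'
#' One object per outcome: `{text, spans: [{start, end, label}]}`, the
#' interchange shape of common span-annotation exporters (0-based,
#' half-open offsets).
#'
#' @param outcomes Outcome table.
#' @param mentions Normalized mentions for those outcomes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions_jsonl <- function(outcomes, mentions, path) {
  keys <- paste(outcomes$study_id, outcomes$outcome_index, sep = ":")
  mkeys <- paste(mentions$study_id, mentions$outcome_index, sep = ":")
  lines <- vapply(seq_len(nrow(outcomes)), function(i) {
    mm <- mentions[mkeys == keys[i], , drop = FALSE]
    spans <- lapply(seq_len(nrow(mm)), function(j) {
      list(start = mm$start[j] - 1L, end = mm$end[j] - 1L,
           label = if (is.na(mm$normalized_instrument_id[j])) "UNNORMALIZED"
                   else mm$normalized_instrument_id[j])
    })
    jsonlite::toJSON(list(text = outcomes$text[i], spans = spans),
                     auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
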