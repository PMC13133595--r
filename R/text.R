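## Text normalization and tokenization shared by the matcher, the NER
## extractor and the similarity code.

DASH_CHARS <- c("‐", "‑", "‒", "–", "—", "−")

#' Normalize an outcome text, keeping an offset map back to the original
#'
#' Case-folds, unifies hyphen/en-dash variants to `-`, collapses runs of
#' whitespace to a single space and trims the ends. The returned offset map
#' converts spans reported against the normalized string back into
#' `[start, end)` character offsets of the original string.
#'
#' @param text A single character string (`NA` is treated as empty).
#' @return A list with elements `text` (normalized string) and `map`
#'   (integer vector, one entry per normalized character, holding the
#'   1-based index of the original character it derives from).
#' @examples
#' normalize_text("EORTC  QLQ–C30")$text
#' @export
normalize_text <- function(text) {
  if (length(text) != 1L) stop("normalize_text() expects a single string")
  if (is.na(text)) text <- ""
  text <- enc2utf8(as.character(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(n)
  map <- integer(n)
  j <- 0L
  pending_space <- FALSE
  ws_first <- 0L
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% DASH_CHARS) ch <- "-"
    if (grepl("[[:space:]]", ch)) {
      if (j > 0L && !pending_space) {
        pending_space <- TRUE
        ws_first <- i  # a separator maps to the first whitespace of the gap
      }
      next
    }
    if (pending_space) {
      j <- j + 1L
      out[j] <- " "
      map[j] <- ws_first
      pending_space <- FALSE
    }
    j <- j + 1L
    out[j] <- tolower(ch)
    map[j] <- i
  }
  list(text = paste0(out[seq_len(j)], collapse = ""), map = map[seq_len(j)])
}

#' @rdname normalize_text
#' @param span Integer vector `c(start, end)`, a half-open span into the
#'   normalized string.
#' @param norm A value returned by [normalize_text()].
#' @return `denormalize_span()`: the corresponding `[start, end)` span in
#'   the original string.
#' @export
denormalize_span <- function(norm, span) {
  start <- span[[1]]
  end <- span[[2]]
  stopifnot(start >= 1L, end > start, end - 1L <= length(norm$map))
  c(norm$map[start], norm$map[end - 1L] + 1L)
}

## Vectorized fold used for similarity and soundness checks: lowercase,
## every non-alphanumeric run becomes a single space, trimmed.
sim_fold <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Tokenize text into word tokens with character spans
#'
#' Whitespace tokenization with punctuation split off as separate tokens;
#' hyphens, slashes, periods and apostrophes *inside* alphanumeric runs are
#' kept (so `QLQ-C30`, `1.1` or `EQ-5D-5L` stay single tokens).
#'
#' @param text A single string.
#' @return A data.frame with columns `token`, `start`, `end` (half-open
#'   character offsets).
#' @export
tokenize_spans <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  pat <- "[[:alnum:]]+(?:[-'./&][[:alnum:]]+)*|[^[:alnum:][:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(token = substring(text, start, start + len - 1L),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

## Character trigram profile of a folded string (counts, named vector).
char_trigrams <- function(x) {
  x <- sim_fold(x)
  n <- nchar(x)
  if (n < 3L) {
    if (n == 0L) return(integer(0))
    tab <- table(x)  # fall back to the whole short string as one "gram"
    return(structure(as.integer(tab), names = names(tab)))
  }
  grams <- substring(x, 1:(n - 2L), 3:n)
  tab <- table(grams)
  structure(as.integer(tab), names = names(tab))
}

#' Character-trigram cosine similarity between two strings
#'
#' Both strings are folded (case, punctuation and whitespace removed into
#' single spaces) before profiling, so the similarity is invariant to case,
#' hyphen/space variation and surrounding whitespace.
#'
#' @param a,b Character strings.
#' @return Cosine similarity in `[0, 1]`.
#' @export
trigram_cosine <- function(a, b) {
  pa <- char_trigrams(a)
  pb <- char_trigrams(b)
  if (length(pa) == 0L || length(pb) == 0L) return(0)
  shared <- intersect(names(pa), names(pb))
  if (length(shared) == 0L) return(0)
  num <- sum(pa[shared] * pb[shared])
  num / sqrt(sum(pa^2) * sum(pb^2))
}
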