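## Independent oracles and small fixtures used across the test files.
## These deliberately re-derive results by brute force, separate from the
## code paths they check.

## --- fixtures ---------------------------------------------------------

tiny_lexicon <- function() {
  instrument_lexicon(data.frame(
    instrument_id = c("eortc_qlq_c30", "hads", "fss", "sf36", "bpi"),
    canonical_name = c(
      "European Organisation for Research and Treatment of Cancer Quality of Life Questionnaire-Core 30",
      "Hospital Anxiety and Depression Scale", "Fatigue Severity Scale",
      "Short Form 36 Health Survey", "Brief Pain Inventory"),
    acronyms = c("EORTC QLQ-C30;QLQ-C30", "HADS", "FSS", "SF-36", "BPI"),
    kind = "PROM", condition_tag = "test",
    stringsAsFactors = FALSE))
}

make_raw_record <- function(id = "NCT00000001", date = "2015-06-01",
                            type = "INTERVENTIONAL", phases = NULL,
                            outcomes = list(list(measure = "Overall survival",
                                                 description = "Time to death")),
                            conditions = list("Breast Cancer"), ...) {
  extra <- list(...)
  design <- list(studyType = type)
  if (!is.null(phases)) design$phases <- phases
  if (!is.null(extra$designInfo)) design$designInfo <- extra$designInfo
  list(protocolSection = list(
    identificationModule = list(nctId = id),
    statusModule = list(startDateStruct = list(date = date)),
    designModule = design,
    conditionsModule = list(conditions = conditions),
    outcomesModule = list(primaryOutcomes = outcomes)))
}

## --- brute-force matcher oracle --------------------------------------

## All spellings of a normalized surface form under the matcher's
## hyphen/space equivalences: "-" may appear as "-", " " or nothing;
## " " may appear as " " or "-".
surface_variants <- function(s) {
  pos <- regexpr("[- ]", s)
  if (pos == -1L) return(s)
  head <- substr(s, 1L, pos - 1L)
  ch <- substr(s, pos, pos)
  tail <- substr(s, pos + 1L, nchar(s))
  reps <- if (ch == "-") c("-", " ", "") else c(" ", "-")
  unlist(lapply(surface_variants(tail), function(t) paste0(head, reps, t)))
}

## Naive fixed-substring scan with boundary and acronym-case checks.
oracle_match <- function(text, lexicon, terms) {
  forms <- promscan:::lexicon_surface_forms(lexicon, terms)
  norm <- normalize_text(text)
  if (!nzchar(norm$text)) return(FALSE)
  for (i in seq_len(nrow(forms))) {
    nf <- normalize_text(forms$surface[i])$text
    needs_case <- forms$source[i] == "instrument_acronym" &&
      nchar(gsub("[^a-zA-Z0-9]", "", forms$surface[i])) <= 4L
    for (v in surface_variants(nf)) {
      start <- 1L
      repeat {
        hit <- regexpr(v, substring(norm$text, start), fixed = TRUE)
        if (hit == -1L) break
        s <- start + as.integer(hit) - 1L
        e <- s + nchar(v)
        before <- if (s > 1L) substring(norm$text, s - 1L, s - 1L) else ""
        after <- if (e <= nchar(norm$text)) substring(norm$text, e, e) else ""
        boundary_ok <- !grepl("[a-z0-9]", before) && !grepl("[a-z0-9]", after)
        if (boundary_ok) {
          if (!needs_case) return(TRUE)
          span <- denormalize_span(norm, c(s, e))
          orig <- substring(text, span[1], span[2] - 1L)
          if (grepl("[0-9]", orig) ||
              (grepl("[A-Za-z]", orig) && identical(orig, toupper(orig)))) {
            return(TRUE)
          }
        }
        start <- s + 1L
      }
    }
  }
  FALSE
}

## --- brute-force kappa from the 2x2 contingency table ----------------

oracle_kappa_2x2 <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  if (n10 == 0L && n01 == 0L && (n11 == 0L || n00 == 0L)) return(1)
  p_o <- (n11 + n00) / n
  p_e <- ((n11 + n10) / n) * ((n11 + n01) / n) +
    ((n01 + n00) / n) * ((n10 + n00) / n)
  (p_o - p_e) / (1 - p_e)
}

## --- brute-force character-trigram cosine -----------------------------

oracle_trigram_cosine <- function(a, b) {
  fold <- function(x) trimws(gsub("[^a-z0-9]+", " ", tolower(x)))
  grams <- function(x) {
    x <- fold(x)
    n <- nchar(x)
    if (n == 0L) return(character(0))
    if (n < 3L) return(x)
    vapply(1:(n - 2L), function(i) substr(x, i, i + 2L), character(1))
  }
  ga <- grams(a)
  gb <- grams(b)
  if (length(ga) == 0L || length(gb) == 0L) return(0)
  u <- unique(c(ga, gb))
  ca <- vapply(u, function(g) sum(ga == g), numeric(1))
  cb <- vapply(u, function(g) sum(gb == g), numeric(1))
  s <- sum(ca * cb)
  if (s == 0) return(0)
  s / sqrt(sum(ca^2) * sum(cb^2))
}

## --- hand-rolled IRLS logistic regression ------------------------------

oracle_irls <- function(x, y, tol = 1e-10, max_iter = 100L) {
  beta <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    xtwx <- t(x) %*% (x * w)
    beta_new <- solve(xtwx, t(x) %*% (w * z))
    if (max(abs(beta_new - beta)) < tol) return(as.numeric(beta_new))
    beta <- as.numeric(beta_new)
  }
  as.numeric(beta)
}

## Labeled corpus built from a generated synthetic corpus.
synthetic_labeled_corpus <- function(g) {
  ot <- outcomes_table(g$studies)
  d <- merge(ot, g$ground_truth$outcomes,
             by = c("study_id", "outcome_index"))
  labeled_corpus(data.frame(
    study_id = d$study_id, outcome_index = d$outcome_index, text = d$text,
    gold_label = as.integer(d$contains_named_instrument),
    stringsAsFactors = FALSE))
}
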