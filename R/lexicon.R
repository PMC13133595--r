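## Instrument lexicon and generic-term list for the expert-style matcher.

#' Construct an instrument lexicon
#'
#' An instrument lexicon holds canonical PROM/PREM instruments with their
#' acronyms; it is the ground truth for both detection and mention
#' normalization. The packaged fixture (see [read_lexicon()]) is a
#' synthetic ~40-entry stand-in for the proprietary 346-entry PROQOLID
#' oncology extract.
#'
#' @param entries A data.frame with columns `instrument_id`,
#'   `canonical_name`, `acronyms` (list column or `;`-separated strings),
#'   `kind` (`"PROM"` or `"PREM"`) and `condition_tag`.
#' @return An object of class `instrument_lexicon`.
#' @export
instrument_lexicon <- function(entries) {
  req <- c("instrument_id", "canonical_name", "acronyms", "kind", "condition_tag")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols) > 0L) {
    stop("lexicon is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!is.list(entries$acronyms)) {
    entries$acronyms <- lapply(strsplit(as.character(entries$acronyms), ";",
                                        fixed = TRUE),
                               function(a) trimws(a[nzchar(trimws(a))]))
  }
  if (anyDuplicated(entries$instrument_id)) {
    stop("instrument_id values must be unique")
  }
  if (any(!nzchar(entries$canonical_name))) {
    stop("canonical_name must be non-empty")
  }
  if (any(vapply(entries$acronyms, function(a) any(!nzchar(a)), logical(1)))) {
    stop("empty acronym strings are not allowed")
  }
  if (!all(entries$kind %in% c("PROM", "PREM"))) {
    stop("kind must be 'PROM' or 'PREM'")
  }
  structure(list(entries = entries), class = "instrument_lexicon")
}

#' Read an instrument lexicon from CSV
#'
#' Expected header: `instrument_id,canonical_name,acronyms,kind,condition_tag`
#' with acronyms separated by semicolons. With no argument, loads the
#' packaged synthetic fixture lexicon.
#'
#' @param path Path to a lexicon CSV; defaults to the packaged fixture.
#' @return An `instrument_lexicon`.
#' @export
read_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "instrument_lexicon_synthetic.csv",
                        package = "promscan", mustWork = TRUE)
  }
  instrument_lexicon(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.instrument_lexicon <- function(x, ...) {
  cat("Instrument lexicon:", nrow(x$entries), "entries (",
      sum(x$entries$kind == "PROM"), "PROM /",
      sum(x$entries$kind == "PREM"), "PREM )\n")
  invisible(x)
}

#' The generic PROM/PREM term lists
#'
#' Eight PROM-specific and three PREM-specific open terms used by the
#' expert-style matcher alongside the instrument lexicon. The defaults are
#' fixed; the term `"QoLd"` is shipped verbatim as published even though it
#' is plausibly a typo for "QoL" — an explicit `"qol"` alias can be enabled
#' with `include_qol_alias = TRUE` (default off).
#'
#' @param include_qol_alias Add `"qol"` to the PROM terms (default `FALSE`).
#' @return A list of class `generic_terms` with `prom_terms` and
#'   `prem_terms` character vectors.
#' @export
generic_terms <- function(include_qol_alias = FALSE) {
  prom <- c("quality of life", "QoLd", "patient-reported outcome",
            "psychometric", "patient perspective", "questionnaire",
            "health related quality of life", "hrql")
  prem <- c("satisfaction", "experience", "quality of care")
  if (isTRUE(include_qol_alias)) prom <- c(prom, "qol")
  structure(list(prom_terms = prom, prem_terms = prem),
            class = "generic_terms")
}

## All surface forms of a lexicon + term list as a flat data.frame
## (source, id, surface). Used by the matcher and by test oracles.
lexicon_surface_forms <- function(lexicon = NULL, terms = NULL) {
  out <- list()
  if (!is.null(lexicon)) {
    e <- lexicon$entries
    out$names <- data.frame(source = "instrument_name",
                            id = e$instrument_id,
                            surface = e$canonical_name,
                            stringsAsFactors = FALSE)
    n_acr <- lengths(e$acronyms)
    out$acronyms <- data.frame(source = "instrument_acronym",
                               id = rep(e$instrument_id, n_acr),
                               surface = unlist(e$acronyms, use.names = FALSE),
                               stringsAsFactors = FALSE)
  }
  if (!is.null(terms)) {
    all_terms <- c(terms$prom_terms, terms$prem_terms)
    out$terms <- data.frame(source = "generic_term",
                            id = all_terms,
                            surface = all_terms,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
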