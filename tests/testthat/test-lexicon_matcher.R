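lex <- read_lexicon()
terms <- generic_terms()

test_that("normalization folds case, dashes and whitespace", {
  expect_equal(normalize_text("EORTC  QLQ–C30")$text, "eortc qlq-c30")
  expect_equal(normalize_text("")$text, "")
  expect_equal(normalize_text("  padded   out  ")$text, "padded out")
})

test_that("reported spans always map inside the original string", {
  set.seed(404)
  alphabet <- c(letters, LETTERS, 0:9, " ", "  ", "-", "–", ".", ",")
  for (rep in 1:50) {
    orig <- paste0(sample(alphabet, sample(3:40, 1), replace = TRUE),
                   collapse = "")
    norm <- normalize_text(orig)
    n <- nchar(norm$text)
    if (n == 0L) next
    for (k in 1:5) {
      s <- sample.int(n, 1)
      e <- s + sample.int(n - s + 1L, 1)
      span <- denormalize_span(norm, c(s, e))
      expect_true(span[1] >= 1L && span[2] <= nchar(orig) + 1L)
      # the original slice folds to the same content as the normalized one
      expect_equal(promscan:::sim_fold(substring(orig, span[1], span[2] - 1L)),
                   promscan:::sim_fold(substring(norm$text, s, e - 1L)))
    }
  }
})

test_that("the default generic-term lists are fixed at 8 + 3", {
  expect_length(terms$prom_terms, 8L)
  expect_length(terms$prem_terms, 3L)
  expect_true("QoLd" %in% terms$prom_terms)  # shipped verbatim, not corrected
  expect_false("qol" %in% terms$prom_terms)
  expect_true("qol" %in% generic_terms(include_qol_alias = TRUE)$prom_terms)
})

test_that("matching finds instruments, acronyms and generic terms", {
  m1 <- match_outcome("Change in EORTC QLQ-C30 global health status at week 12",
                      lex, terms)
  expect_true(m1$matched)
  expect_equal(m1$hits$source, "instrument_acronym")
  expect_equal(m1$hits$id, "eortc_qlq_c30")
  expect_equal(m1$hits$matched_text, "EORTC QLQ-C30")

  m2 <- match_outcome("Patient satisfaction with nursing care", lex, terms)
  expect_true(m2$matched)
  expect_equal(m2$hits$source, "generic_term")
  expect_equal(m2$hits$id, "satisfaction")

  expect_false(match_outcome("Objective response rate per RECIST 1.1",
                             lex, terms)$matched)
  # an uppercase symptom word is not an instrument under word-boundary
  # matching with the acronym-case rule
  expect_false(match_outcome("PAIN intensity recorded by the clinician",
                             lex, terms)$matched)
  # lowercase prose colliding with a short acronym must not fire either
  expect_false(match_outcome("in fact the schedule changed", lex, terms)$matched)
  # hyphen variants of a multiword name are matched
  expect_true(match_outcome("Scores on the EORTC QLQ C30", lex, terms)$matched)
  # the qol alias only fires when enabled
  expect_false(match_outcome("Improvement in QoL at 3 months", lex, terms)$matched)
  expect_true(match_outcome("Improvement in QoL at 3 months", lex,
                            generic_terms(include_qol_alias = TRUE))$matched)
})

test_that("an empty lexicon and term list is a configuration error", {
  expect_error(match_outcome("anything", NULL, NULL), "configuration")
})

test_that("hits are sound, spans valid, and matching deterministic", {
  texts <- c("Change in EORTC QLQ-C30 and HADS total score",
             "Hospital Anxiety and Depression Scale questionnaire scores",
             "satisfaction with quality of care experience")
  for (text in texts) {
    r1 <- match_outcome(text, lex, terms)
    r2 <- match_outcome(text, lex, terms)
    expect_identical(r1, r2)
    forms <- promscan:::lexicon_surface_forms(lex, terms)
    folded <- promscan:::sim_fold(forms$surface)
    for (i in seq_len(nrow(r1$hits))) {
      expect_true(r1$hits$start[i] >= 1 &&
                    r1$hits$end[i] <= nchar(text) + 1)
      expect_true(promscan:::sim_fold(r1$hits$matched_text[i]) %in% folded)
    }
    # matched iff hits non-empty
    expect_equal(r1$matched, nrow(r1$hits) > 0L)
  }
})

test_that("overlapping hits keep the longest span", {
  # "Quality of Life Questionnaire-Core 30" contains the generic term
  # "quality of life"; the instrument hit must win
  m <- match_outcome("European Organisation for Research and Treatment of Cancer Quality of Life Questionnaire-Core 30",
                     lex, terms)
  expect_true(m$matched)
  expect_equal(m$hits$source, "instrument_name")
  expect_equal(nrow(m$hits), 1L)
})

test_that("adding a lexicon entry never unmatches an outcome", {
  g <- generate_corpus(synthetic_config(n_studies = 60, seed = 21))
  ot <- outcomes_table(g$studies)
  base <- flag_corpus(ot, lex, terms)$flags
  extended <- instrument_lexicon(rbind(
    lex$entries,
    data.frame(instrument_id = "zzz_new",
               canonical_name = "Zzz Wellness Profile",
               acronyms = I(list("ZZWP")), kind = "PROM",
               condition_tag = "test")))
  ext <- flag_corpus(ot, extended, terms)$flags
  expect_true(all(ext$matched[base$matched]))
})

test_that("corpus flagging summarizes and matches the planted truth", {
  cfg <- synthetic_config(n_studies = 40, seed = 33,
                          variant_rates = list(acronym_only = 0.3,
                                               hyphen_drop = 0,
                                               fragment_multiword = 0,
                                               typo = 0))
  g <- generate_corpus(cfg)
  ot <- outcomes_table(g$studies)
  fc <- flag_corpus(ot, lex, terms)
  expect_equal(sum(fc$summary), nrow(ot))
  m <- merge(fc$flags, g$ground_truth$outcomes,
             by = c("study_id", "outcome_index"))
  expect_equal(mean(m$matched[m$contains_named_instrument]), 1)
  # empty corpus
  fc0 <- flag_corpus(ot[0, ], lex, terms)
  expect_equal(unname(fc0$summary), c(0L, 0L))
})

test_that("the matcher agrees with a brute-force substring oracle", {
  small_lex <- tiny_lexicon()
  cfg <- synthetic_config(
    n_studies = 60, seed = 77,
    instrument_mix = c(eortc_qlq_c30 = 1, hads = 1, fss = 1, sf36 = 1,
                       bpi = 1))
  g <- generate_corpus(cfg)
  ot <- outcomes_table(g$studies)
  fc <- flag_corpus(ot, small_lex, terms)
  oracle <- vapply(ot$text, oracle_match, logical(1),
                   lexicon = small_lex, terms = terms)
  expect_equal(unname(fc$flags$matched), unname(oracle))
})
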