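lex <- read_lexicon()

test_that("span-to-BIO tagging follows the scheme under the tokenizer", {
  b <- spans_to_bio("Assessed by EORTC QLQ-C30 at baseline",
                    data.frame(start = 13, end = 26))
  expect_equal(b$tags, c("O", "O", "B", "I", "O", "O"))
  expect_equal(b$tokens[b$tags == "B"], "EORTC")

  all_o <- spans_to_bio("No instrument here", data.frame(start = integer(0),
                                                         end = integer(0)))
  expect_true(all(all_o$tags == "O"))
  expect_error(spans_to_bio("some text here",
                            data.frame(start = c(1, 3), end = c(5, 8))),
               "overlap")
})

test_that("BIO validity is enforced on decoding", {
  bad <- structure(list(tokens = c("a", "b"), tags = c("O", "I"),
                        starts = c(1L, 3L), ends = c(2L, 4L)),
                   class = "bio_sequence")
  expect_error(bio_to_spans(bad), "invalid BIO")
})

test_that("spans survive a BIO round trip on randomized span sets", {
  set.seed(99)
  words <- c("eortc", "qlq-c30", "score", "at", "baseline", "hads",
             "change", "week", "12", "total", "survey", "form")
  for (i in 1:200) {
    text <- paste(sample(words, sample(4:12, 1), replace = TRUE),
                  collapse = " ")
    toks <- tokenize_spans(text)
    n <- nrow(toks)
    spans <- data.frame(start = integer(0), end = integer(0))
    free <- seq_len(n)
    for (k in seq_len(sample(0:3, 1))) {
      if (length(free) == 0) break
      s <- free[sample.int(length(free), 1)]
      len <- sample(1:min(3, max(free) - s + 1), 1)
      idx <- s:(s + len - 1)
      if (!all(idx %in% free)) next
      spans <- rbind(spans, data.frame(start = toks$start[s],
                                       end = toks$end[s + len - 1]))
      free <- setdiff(free, c(idx, max(idx) + 1L))  # keep spans non-adjacent
    }
    spans <- spans[order(spans$start), , drop = FALSE]
    rownames(spans) <- NULL
    got <- bio_to_spans(spans_to_bio(text, spans))
    expect_equal(got, spans)
  }
})

test_that("the rule-assisted extractor merges fragmented multiword names", {
  text <- "Scores on the Short Form 36 Health Survey at 12 weeks"
  # a weak extractor that fragments the name into two pieces
  weak <- function(t) data.frame(start = c(15, 29), end = c(25, 42))
  got <- extract_mentions(text, extractor = weak)
  expect_equal(nrow(got), 1L)
  expect_equal(got$surface_text, "Short Form 36 Health Survey")
  # and the built-in rules find it in one piece as well
  own <- extract_mentions(text, lex)
  expect_true("Short Form 36 Health Survey" %in% own$surface_text)
})

test_that("texts without instrument-like tokens yield no mentions", {
  expect_equal(nrow(extract_mentions("time to disease progression", lex)), 0L)
  expect_equal(nrow(extract_mentions("", lex)), 0L)
})

test_that("normalization assigns by trigram cosine with threshold and ties", {
  exact <- normalize_mention(
    list(surface_text = "Hospital Anxiety and Depression Scale",
         start = 1, end = 38), lex)
  expect_equal(exact$similarity, 1)
  expect_equal(exact$normalized_instrument_id, "hads")

  hyphenless <- normalize_mention(
    list(surface_text = "EORTC QLQ C30", start = 1, end = 14), lex)
  expect_equal(hyphenless$normalized_instrument_id, "eortc_qlq_c30")
  expect_gte(hyphenless$similarity, 0.85)

  pain <- normalize_mention(list(surface_text = "PAIN", start = 1, end = 5),
                            lex)
  expect_true(is.na(pain$normalized_instrument_id))
  expect_lt(pain$similarity, 0.85)

  # ties break toward the lexicographically smallest instrument id
  twin <- instrument_lexicon(data.frame(
    instrument_id = c("b_twin", "a_twin"),
    canonical_name = "Alpha Beta Scale",
    acronyms = c("ABS", "ABS"), kind = "PROM", condition_tag = "t"))
  tied <- normalize_mention(list(surface_text = "Alpha Beta Scale",
                                 start = 1, end = 17), twin)
  expect_equal(tied$normalized_instrument_id, "a_twin")

  expect_error(normalize_mention(list(surface_text = "x", start = 1, end = 2),
                                 lex, threshold = 0), "threshold")
})

test_that("similarity matches a brute-force oracle and is fold-invariant", {
  pairs <- list(c("EORTC QLQ C30", "EORTC QLQ-C30"),
                c("PAIN", "Brief Pain Inventory"),
                c("hospital anxiety and depression scale",
                  "Hospital Anxiety and Depression Scale"),
                c("FACT-G", "Functional Assessment of Cancer Therapy - General"),
                c("SF 36", "SF-36"))
  for (p in pairs) {
    expect_equal(trigram_cosine(p[1], p[2]),
                 oracle_trigram_cosine(p[1], p[2]), tolerance = 1e-12)
  }
  expect_equal(trigram_cosine("  EORTC   QLQ-C30 ", "eortc qlq c30"), 1)
})

test_that("instrument frequencies count once per study", {
  mentions <- data.frame(
    study_id = c("S1", "S1", "S2"), outcome_index = c(1L, 2L, 1L),
    surface_text = "EORTC QLQ-C30", start = 1L, end = 14L,
    normalized_instrument_id = "eortc_qlq_c30", similarity = 1,
    stringsAsFactors = FALSE)
  tab <- instrument_frequencies(mentions)
  expect_equal(tab$n_studies, 2L)  # S1 deduplicated
  expect_equal(tab$proportion, 1)
  empty <- instrument_frequencies(mentions[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("planted instrument frequencies are recovered exactly", {
  cfg <- synthetic_config(n_studies = 60, seed = 14,
                          variant_rates = list(acronym_only = 0.4,
                                               hyphen_drop = 0.1,
                                               fragment_multiword = 0,
                                               typo = 0))
  g <- generate_corpus(cfg)
  ot <- outcomes_table(g$studies)
  mentions <- corpus_mentions(ot, lex)
  got <- instrument_frequencies(mentions)
  want <- corpus_report(g$ground_truth)$instrument_frequencies
  got <- got[order(got$instrument_id), c("instrument_id", "n_studies")]
  want <- want[order(want$instrument_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("mention export writes parseable 0-based span annotations", {
  ot <- data.frame(study_id = "S1", outcome_index = 1L,
                   text = "Change in HADS total score")
  mentions <- corpus_mentions(ot, lex)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_mentions_jsonl(ot, mentions, path)
  line <- jsonlite::fromJSON(readLines(path)[1], simplifyVector = FALSE)
  expect_equal(line$text, ot$text)
  sp <- line$spans[[1]]
  expect_equal(substr(ot$text, sp$start + 1, sp$end), "HADS")
  expect_equal(sp$label, "hads")
})
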