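make_corpus <- function(n_pos, n_neg, pos_word = "toolkit") {
  labeled_corpus(data.frame(
    study_id = sprintf("S%04d", seq_len(n_pos + n_neg)),
    outcome_index = 1L,
    text = c(sprintf("assessment using the %s form item %d", pos_word,
                     seq_len(n_pos)),
             sprintf("overall survival endpoint number %d", seq_len(n_neg))),
    gold_label = rep(c(1L, 0L), c(n_pos, n_neg)),
    stringsAsFactors = FALSE))
}

test_that("class balancing downsamples the majority class", {
  corpus <- make_corpus(60, 40)
  bal <- balance_classes(corpus, seed = 1)
  expect_equal(unname(table(bal$gold_label)), c(40L, 40L), ignore_attr = TRUE)
  even <- make_corpus(40, 40)
  expect_equal(balance_classes(even, seed = 1), even)
  expect_identical(balance_classes(corpus, seed = 7),
                   balance_classes(corpus, seed = 7))
  expect_false(identical(balance_classes(corpus, seed = 7),
                         balance_classes(corpus, seed = 8)))
  single <- labeled_corpus(data.frame(study_id = "A", outcome_index = 1L,
                                      text = "x", gold_label = 1L))
  expect_error(balance_classes(single, seed = 1), "both classes")
})

test_that("split sizes follow largest-remainder apportionment", {
  corpus <- make_corpus(5, 5)
  sp <- split_corpus(corpus, ratios = c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(unname(attr(sp, "sizes")), c(6L, 2L, 2L))
  all_train <- split_corpus(corpus, ratios = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$subset == "train"))
  expect_error(split_corpus(corpus, ratios = c(0.5, 0.2, 0.2), seed = 1),
               "summing to 1")
})

test_that("the published explicit counts are accepted and consistent", {
  corpus <- make_corpus(1972, 1971)  # 3943 items
  sp <- split_corpus(corpus, seed = 3, sizes = c(2399, 479, 1065))
  sizes <- attr(sp, "sizes")
  expect_equal(unname(sizes), c(2399L, 479L, 1065L))
  expect_equal(sum(sizes), 3943L)
  # each achieved size rounds to the printed percentage split 61/12/27
  expect_equal(round(100 * sizes / 3943), c(61, 12, 27), ignore_attr = TRUE)
})

test_that("splits partition the corpus and stratify by label", {
  corpus <- make_corpus(130, 270)
  sp <- split_corpus(corpus, seed = 5)
  expect_equal(sort(table(sp$subset), decreasing = TRUE)[1:3],
               sort(attr(sp, "sizes"), decreasing = TRUE)[1:3],
               ignore_attr = TRUE)
  expect_equal(nrow(sp), nrow(corpus))
  ratios <- attr(sp, "ratios")
  for (cl in 0:1) {
    n_cl <- sum(corpus$gold_label == cl)
    for (i in 1:3) {
      part <- c("train", "validation", "test")[i]
      got <- sum(sp$subset == part & sp$gold_label == cl)
      expect_lte(abs(got - ratios[i] * n_cl), 1 + 1e-9)
    }
  }
})

test_that("training selects the validation-accuracy argmax", {
  corpus <- make_corpus(80, 80)
  sp <- split_corpus(corpus, seed = 2)
  one <- train_classifier(sp, grid = list(list(lambda = 1e-3)))
  expect_equal(one$selected, 1L)
  expect_equal(nrow(one$report), 1L)
  model <- train_classifier(sp)
  expect_equal(model$selected, which.max(model$report$val_accuracy))
  expect_error(train_classifier(sp, grid = list()), "non-empty")
  no_val <- split_corpus(corpus, ratios = c(1, 0, 0), seed = 2)
  expect_error(train_classifier(no_val), "validation")
})

test_that("a tiny training positive is memorized by the baseline backend", {
  corpus <- make_corpus(10, 10)
  sp <- split_corpus(corpus, ratios = c(0.8, 0.2, 0), seed = 1)
  model <- train_classifier(sp, grid = list(list(lambda = 1e-4)))
  train_pos <- sp$text[sp$subset == "train" & sp$gold_label == 1][1]
  expect_equal(predict(model, train_pos)$label, 1L)
})

test_that("prediction is total, bounded, and monotone in the decisive token", {
  corpus <- make_corpus(50, 50)
  sp <- split_corpus(corpus, seed = 4)
  model <- train_classifier(sp)
  p <- predict(model, c("", "some unrelated text", NA_character_))
  expect_equal(nrow(p), 3L)
  expect_true(all(p$score >= 0 & p$score <= 1))
  reps <- vapply(1:4, function(k) {
    predict(model, paste(rep("toolkit", k), collapse = " "))$score
  }, numeric(1))
  expect_true(all(diff(reps) >= 0))
  expect_identical(predict(model, corpus$text), predict(model, corpus$text))
})

test_that("classifier artifacts round-trip through the text format", {
  corpus <- make_corpus(40, 40)
  sp <- split_corpus(corpus, seed = 6)
  model <- train_classifier(sp)
  dir <- withr::local_tempdir()
  write_classifier(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_classifier(dir)
  expect_equal(predict(back, corpus$text), predict(model, corpus$text))
})
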