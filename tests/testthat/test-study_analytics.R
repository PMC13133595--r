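test_that("study flags are the OR over outcome flags", {
  flags <- data.frame(study_id = c("A", "A", "A", "B", "B"),
                      matched = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  agg <- aggregate_study_flags(flags)
  expect_equal(agg$uses_prompem[agg$study_id == "A"], 1L)
  expect_equal(agg$uses_prompem[agg$study_id == "B"], 0L)
  # adding a positive outcome never flips yes -> no
  flags2 <- rbind(flags, data.frame(study_id = "A", matched = TRUE))
  expect_equal(aggregate_study_flags(flags2)$uses_prompem[1], 1L)
  expect_error(aggregate_study_flags(data.frame(study_id = "A",
                                                matched = NA)),
               "flag")
  # brute-force any() agreement on a generated corpus
  g <- generate_corpus(synthetic_config(n_studies = 100, seed = 31))
  gt <- g$ground_truth$outcomes
  agg2 <- aggregate_study_flags(data.frame(study_id = gt$study_id,
                                           matched = gt$contains_named_instrument))
  brute <- vapply(split(gt$contains_named_instrument, gt$study_id), any,
                  logical(1))
  expect_equal(agg2$uses_prompem, as.integer(brute[agg2$study_id]),
               ignore_attr = TRUE)
})

test_that("the analytics table refuses studies without flags", {
  g <- generate_corpus(synthetic_config(n_studies = 10, seed = 2))
  flags <- aggregate_study_flags(data.frame(
    study_id = g$ground_truth$outcomes$study_id,
    matched = g$ground_truth$outcomes$contains_named_instrument))
  expect_error(study_analytics_table(g$studies, flags[-1, ]), "upstream")
  tab <- study_analytics_table(g$studies, flags)
  expect_equal(nrow(tab), 10L)
})

test_that("yearly trend detects a planted increase and not a flat null", {
  set.seed(1234)
  flat <- data.frame(year = rep(2012:2021, each = 200),
                     uses_prompem = rbinom(2000, 1, 0.5))
  yt_flat <- yearly_trend(flat)
  expect_gt(yt_flat$trend$p_value, 0.05)

  years <- rep(2012:2021, each = 500)
  p <- 0.25 + 0.15 * (years - 2012) / 9
  rising <- data.frame(year = years, uses_prompem = rbinom(5000, 1, p))
  yt <- yearly_trend(rising)
  expect_lt(yt$trend$p_value, 0.001)
  expect_gt(cor(yt$by_year$year, yt$by_year$proportion, method = "spearman"),
            0.8)

  empty <- yearly_trend(flat[0, ])
  expect_equal(nrow(empty$by_year), 0L)
  expect_null(empty$trend)
  single <- yearly_trend(data.frame(year = 2015, uses_prompem = c(0, 1)))
  expect_null(single$trend)
  expect_equal(single$by_year$proportion, 0.5)
})

test_that("bivariate chi-square holds its type-I error under independence", {
  set.seed(55)
  rejections <- 0L
  for (i in 1:1000) {
    tab <- data.frame(x = sample(c("a", "b"), 200, replace = TRUE),
                      uses_prompem = rbinom(200, 1, 0.4))
    res <- bivariate_chisq(tab, "x")
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.075)
})

test_that("bivariate chi-square edge cases", {
  # perfect association in a 2x2 with n = 40 gives statistic n * phi^2 = 40
  tab <- data.frame(x = rep(c("a", "b"), each = 20),
                    uses_prompem = rep(c(1L, 0L), each = 20))
  expect_equal(bivariate_chisq(tab, "x")$statistic, 40)
  # missing level is excluded before testing
  tab2 <- rbind(tab, data.frame(x = "missing", uses_prompem = 1L))
  expect_equal(bivariate_chisq(tab2, "x")$statistic, 40)
  one_level <- data.frame(x = "a", uses_prompem = c(0L, 1L))
  expect_error(bivariate_chisq(one_level, "x"), "levels")
})

test_that("logistic regression matches a hand-rolled IRLS reference", {
  set.seed(77)
  n <- 500
  d <- data.frame(
    study_type = "interventional",
    allocation = sample(c("randomized", "nonrandomized"), n, replace = TRUE),
    phase = sample(c("phase1", "phase2", "phase3"), n, replace = TRUE))
  eta <- -0.5 + 0.7 * (d$allocation == "randomized") +
    0.4 * (d$phase == "phase3")
  d$uses_prompem <- rbinom(n, 1, plogis(eta))
  class(d) <- c("study_analytics_table", "data.frame")
  fm <- fit_use_model(d, "interventional", c("allocation", "phase"),
                      reference = list(allocation = "nonrandomized",
                                       phase = "phase1"))
  x <- model.matrix(~ relevel(factor(d$allocation), "nonrandomized") +
                      relevel(factor(d$phase), "phase1"))
  beta <- oracle_irls(x, d$uses_prompem)
  got <- log(fm$or_table$odds_ratio[!fm$or_table$is_reference])
  expect_equal(got, beta[-1], tolerance = 1e-6, ignore_attr = TRUE)
  # reference rows are exactly 1
  expect_true(all(fm$or_table$odds_ratio[fm$or_table$is_reference] == 1))
})

test_that("degenerate model inputs raise informative errors", {
  d <- data.frame(study_type = "interventional",
                  allocation = "randomized",
                  uses_prompem = rbinom(50, 1, 0.5))
  class(d) <- c("study_analytics_table", "data.frame")
  expect_error(fit_use_model(d, "interventional", "allocation"),
               "constant")
  expect_error(fit_use_model(d, "observational", "allocation"),
               "empty stratum")
  # complete separation is reported, naming a term
  d2 <- data.frame(study_type = "interventional",
                   allocation = rep(c("randomized", "nonrandomized"), each = 30),
                   uses_prompem = rep(c(1L, 0L), each = 30))
  class(d2) <- c("study_analytics_table", "data.frame")
  expect_error(fit_use_model(d2, "interventional", "allocation"),
               "separation")
})

test_that("missing rows are dropped from the model with a logged count", {
  set.seed(12)
  n <- 400
  d <- data.frame(
    study_type = "interventional",
    allocation = sample(c("randomized", "nonrandomized", "missing",
                          "not_applicable"), n, replace = TRUE),
    uses_prompem = rbinom(n, 1, 0.4))
  class(d) <- c("study_analytics_table", "data.frame")
  fm <- fit_use_model(d, "interventional", "allocation",
                      reference = list(allocation = "nonrandomized"))
  n_excluded <- sum(d$allocation %in% c("missing", "not_applicable"))
  expect_equal(fm$n_dropped_missing, n_excluded)
  expect_equal(fm$n_used, n - n_excluded)
})

test_that("the MCAR check flags covariate-driven missingness only", {
  set.seed(31)
  n <- 2000
  year <- sample(2012:2021, n, replace = TRUE)
  # missingness strongly driven by year
  miss <- rbinom(n, 1, plogis(-4 + 0.45 * (year - 2012)))
  d <- data.frame(year = year,
                  phase = ifelse(miss == 1, "missing", "phase2"))
  got <- missingness_check(d, "phase", covariates = "year")
  expect_equal(got$verdict, "not MCAR")
  # fully observed
  d2 <- data.frame(year = year, phase = "phase2")
  expect_equal(missingness_check(d2, "phase")$verdict, "nothing to test")
  # independent missingness: rejection rate near the nominal 5%
  rejections <- 0L
  for (i in 1:200) {
    d3 <- data.frame(year = sample(2012:2021, 300, replace = TRUE),
                     phase = ifelse(rbinom(300, 1, 0.3) == 1, "missing",
                                    "phase2"))
    if (missingness_check(d3, "phase")$test_p < 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_gt(rejections / 200, 0.005)
  expect_lt(rejections / 200, 0.12)
})

test_that("p values print in the table convention", {
  expect_equal(format_p(0.0004), "<.001")
  expect_equal(format_p(0.043), ".04")
  expect_equal(format_p(0.5), ".50")
})
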