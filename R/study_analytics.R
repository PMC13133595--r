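## Study-level uptake analytics: aggregation of outcome detections,
## yearly trends, bivariate chi-squares, stratified multivariate logistic
## regression with Wald CIs, and a regression-based MCAR check.

#' Aggregate outcome-level detections into a per-study flag
#'
#' A study is flagged as using at least one PROM or PREM when any of its
#' outcomes is flagged (logical OR over outcomes).
#'
#' @param flags Data.frame with `study_id` and `matched` (one row per
#'   outcome; every outcome must carry a flag).
#' @return Data.frame `study_id`, `uses_prompem` (0/1), one row per study.
#' @export
aggregate_study_flags <- function(flags) {
  if (nrow(flags) == 0L) {
    return(data.frame(study_id = character(0), uses_prompem = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (any(is.na(flags$matched))) {
    stop("every outcome must carry a detection flag")
  }
  agg <- tapply(flags$matched, flags$study_id, any)
  data.frame(study_id = names(agg), uses_prompem = as.integer(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the study analytics table
#'
#' One row per study: the detection flag joined with design covariates
#' (categorical, with an explicit `"missing"` level) and the start year.
#'
#' @param studies List of `study_record` objects.
#' @param study_flags Output of [aggregate_study_flags()].
#' @param site_labels Optional data.frame `study_id`, `site_label`.
#' @return Data.frame of class `study_analytics_table`.
#' @export
study_analytics_table <- function(studies, study_flags, site_labels = NULL) {
  field <- function(name) vapply(studies, function(s) s[[name]], character(1))
  tab <- data.frame(
    study_id = field("study_id"),
    year = as.integer(format(as.Date(vapply(studies, function(s) {
      format(s$start_date)
    }, character(1))), "%Y")),
    study_type = field("study_type"), phase = field("phase"),
    allocation = field("allocation"),
    intervention_model = field("intervention_model"),
    primary_purpose = field("primary_purpose"),
    observational_model = field("observational_model"),
    time_perspective = field("time_perspective"),
    stringsAsFactors = FALSE)
  orphan <- setdiff(tab$study_id, study_flags$study_id)
  if (length(orphan) > 0L) {
    stop("studies without any flagged outcome (should have been filtered ",
         "upstream): ", paste(utils::head(orphan, 5), collapse = ", "))
  }
  tab <- merge(tab, study_flags, by = "study_id")
  if (!is.null(site_labels)) tab <- merge(tab, site_labels, by = "study_id",
                                          all.x = TRUE)
  if (anyDuplicated(tab$study_id)) stop("one row per study expected")
  class(tab) <- c("study_analytics_table", "data.frame")
  tab
}

#' Yearly uptake proportions and trend test
#'
#' Proportion of flagged studies per start year, with a Cochran-Armitage
#' style trend test (score test on year as a linear predictor,
#' [stats::prop.trend.test()]). With a single populated year the
#' proportions are returned without a test.
#'
#' @param table A data.frame with `year` and `uses_prompem`.
#' @return List with `by_year` (data.frame `year`, `n`, `n_using`,
#'   `proportion`) and `trend` (`statistic`, `p_value`, or `NULL` when
#'   untestable).
#' @export
yearly_trend <- function(table) {
  if (nrow(table) == 0L) {
    return(list(by_year = data.frame(year = integer(0), n = integer(0),
                                     n_using = integer(0),
                                     proportion = numeric(0)),
                trend = NULL))
  }
  years <- sort(unique(table$year))
  n <- vapply(years, function(y) sum(table$year == y), integer(1))
  n_using <- as.integer(vapply(years, function(y) {
    sum(table$uses_prompem[table$year == y])
  }, numeric(1)))
  by_year <- data.frame(year = years, n = n, n_using = n_using,
                        proportion = n_using / n)
  trend <- NULL
  if (length(years) > 1L) {
    tt <- stats::prop.trend.test(n_using, n, score = years)
    trend <- list(statistic = unname(tt$statistic),
                  p_value = tt$p.value)
  }
  list(by_year = by_year, trend = trend)
}

#' Bivariate chi-square of a covariate against the study flag
#'
#' Pearson chi-square (no continuity correction) on the covariate x flag
#' contingency table, with the `"missing"` level excluded (published
#' convention: P values do not account for missing data).
#'
#' @param table Analytics table.
#' @param covariate Column name.
#' @return List with `statistic`, `df`, `p_value`, `table`.
#' @export
bivariate_chisq <- function(table, covariate) {
  x <- table[[covariate]]
  keep <- !is.na(x) & x != "missing"
  x <- x[keep]
  y <- table$uses_prompem[keep]
  if (length(unique(x)) < 2L) {
    stop("covariate '", covariate, "' has fewer than 2 non-missing levels")
  }
  obs <- table(x, factor(y, levels = c(0L, 1L)))
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expected == 0)) stop("zero expected cell count")
  stat <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), table = obs)
}

#' Stratified multivariate logistic regression of PROM/PREM use
#'
#' Maximum-likelihood logistic regression of the study flag on all
#' predictors jointly within one stratum (interventional or
#' observational), complete-case: rows with a missing value (explicit
#' `"missing"` level or `NA`) in any predictor are dropped with a logged
#' count. Allocation `"not_applicable"` rows (single-group/sequential
#' designs) are likewise structurally excluded when `allocation` is a
#' predictor. Exponentiated coefficients with 95% Wald CIs and Wald p
#' values; reference levels are reported with OR fixed at 1.
#'
#' @param table Analytics table.
#' @param stratum `"interventional"` or `"observational"`.
#' @param predictors Character vector of covariate column names.
#' @param reference Optional named list mapping predictor -> reference
#'   level (default: first level alphabetically).
#' @return List with `or_table` (data.frame of `or_result` rows),
#'   `n_used`, `n_dropped_missing`, and the fitted `model`.
#' @export
fit_use_model <- function(table, stratum = c("interventional",
                                             "observational"),
                          predictors, reference = list()) {
  stratum <- match.arg(stratum)
  d <- table[table$study_type == stratum, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty stratum: ", stratum)
  drop_levels <- c("missing", NA)
  complete <- rep(TRUE, nrow(d))
  for (p in predictors) {
    bad <- is.na(d[[p]]) | d[[p]] %in% "missing"
    if (p == "allocation") bad <- bad | d[[p]] %in% "not_applicable"
    complete <- complete & !bad
  }
  n_dropped <- sum(!complete)
  d <- d[complete, , drop = FALSE]
  if (nrow(d) == 0L) stop("no complete cases in stratum")
  for (p in predictors) {
    lev <- sort(unique(d[[p]]))
    if (length(lev) < 2L) {
      stop("predictor '", p, "' is constant within the stratum; ",
           "the model is not identifiable")
    }
    ref <- reference[[p]] %||% lev[1]
    d[[p]] <- stats::relevel(factor(d[[p]], levels = lev), ref = ref)
  }
  form <- stats::as.formula(paste("uses_prompem ~",
                                  paste(predictors, collapse = " + ")))
  fit <- stats::glm(form, data = d, family = stats::binomial())
  if (!fit$converged) stop("logistic regression did not converge")
  co <- summary(fit)$coefficients
  if (any(abs(co[, "Estimate"]) > 10)) {
    worst <- rownames(co)[which.max(abs(co[, "Estimate"]))]
    stop("apparent separation involving term '", worst, "'")
  }
  rows <- list()
  for (p in predictors) {
    lev <- levels(d[[p]])
    for (l in lev) {
      term <- paste0(p, l)
      if (l == lev[1]) {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = stratum, predictor = p, level = l,
          reference_level = lev[1], odds_ratio = 1, ci_lo = NA_real_,
          ci_hi = NA_real_, wald_p = NA_real_, is_reference = TRUE,
          stringsAsFactors = FALSE)
      } else {
        est <- co[term, "Estimate"]
        se <- co[term, "Std. Error"]
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = stratum, predictor = p, level = l,
          reference_level = lev[1], odds_ratio = exp(est),
          ci_lo = exp(est - 1.959964 * se), ci_hi = exp(est + 1.959964 * se),
          wald_p = co[term, "Pr(>|z|)"], is_reference = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(or_table = do.call(rbind, rows), n_used = nrow(d),
       n_dropped_missing = n_dropped, model = fit)
}

#' Regression-based missing-completely-at-random check
#'
#' Logistic regression of the missingness indicator of `variable` on the
#' fully observed covariates; the verdict is "consistent with MCAR" iff
#' the joint Wald test of all covariate coefficients has p >= 0.05. A
#' fully observed variable returns verdict "nothing to test".
#'
#' @param table Analytics table.
#' @param variable Column whose missingness (`"missing"` level or `NA`)
#'   is checked.
#' @param covariates Fully observed covariate columns (default `year`).
#' @return List with `test_p` and `verdict`.
#' @export
missingness_check <- function(table, variable, covariates = "year") {
  miss <- as.integer(is.na(table[[variable]]) | table[[variable]] == "missing")
  if (all(miss == 0L)) return(list(test_p = NA_real_,
                                   verdict = "nothing to test"))
  if (all(miss == 1L)) stop("variable is entirely missing")
  d <- table
  d$.miss <- miss
  form <- stats::as.formula(paste(".miss ~",
                                  paste(covariates, collapse = " + ")))
  fit <- stats::glm(form, data = d, family = stats::binomial())
  beta <- stats::coef(fit)[-1]
  v <- stats::vcov(fit)[-1, -1, drop = FALSE]
  stat <- as.numeric(t(beta) %*% solve(v) %*% beta)
  p <- stats::pchisq(stat, df = length(beta), lower.tail = FALSE)
  list(test_p = p,
       verdict = if (p >= 0.05) "consistent with MCAR" else "not MCAR")
}

#' Format a p value the way the tables print it
#'
#' `"<.001"` below threshold, two decimals otherwise.
#'
#' @param p Numeric p value.
#' @return Character.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.2f", p)))
}
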