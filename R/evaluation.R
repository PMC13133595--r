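## Scoring detectors against the gold standard: confusion matrix, the five
## headline metrics with confidence intervals, and the between-algorithm
## chi-square comparison.

#' Build a confusion matrix from predicted and gold binary vectors
#'
#' @param predicted,gold Equal-length binary vectors (0/1 or logical);
#'   1 = "uses a PROM or PREM".
#' @return An object of class `confusion_matrix` with integer cells `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    stop("predicted and gold vectors must have equal length")
  }
  if (length(predicted) < 1L) stop("vectors must be non-empty")
  p <- as.integer(as.logical(predicted))
  g <- as.integer(as.logical(gold))
  confusion_matrix(tp = sum(p == 1L & g == 1L), fp = sum(p == 1L & g == 0L),
                   fn = sum(p == 0L & g == 1L), tn = sum(p == 0L & g == 0L))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative integer cell counts (predicted x gold).
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("yes", "no"),
                              gold = c("yes", "no")))
  print(m)
  invisible(x)
}

## Percent rounding used throughout: half away from zero (90.05 -> 90,
## 90.91 -> 91, 89.27 -> 89).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

ci_prop <- function(x, n, method, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  } else {  # wilson
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- center - half
    hi <- center + half
  }
  c(max(0, lo), min(1, hi))
}

#' Compute accuracy, sensitivity, specificity, PPV and NPV with CIs
#'
#' Metrics with an undefined denominator are reported as `NA` with an
#' explicit `undefined` marker, never as 0. The percent view rounds half
#' away from zero.
#'
#' @param cm A `confusion_matrix`.
#' @param ci_method `"wald"` (default) or `"wilson"`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `metrics_report`: data.frame with columns
#'   `metric`, `value`, `lo`, `hi`, `numerator`, `denominator`,
#'   `undefined`, `percent`, `percent_lo`, `percent_hi`, plus attribute
#'   `n`.
#' @export
metrics <- function(cm, ci_method = c("wald", "wilson"), level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0L) stop("empty confusion matrix")
  defs <- list(
    accuracy    = c(cm$tp + cm$tn, n),
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv         = c(cm$tp, cm$tp + cm$fp),
    npv         = c(cm$tn, cm$tn + cm$fn))
  rows <- lapply(names(defs), function(m) {
    num <- defs[[m]][1]
    den <- defs[[m]][2]
    if (den == 0L) {
      return(data.frame(metric = m, value = NA_real_, lo = NA_real_,
                        hi = NA_real_, numerator = num, denominator = den,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    ci <- ci_prop(num, den, ci_method, level)
    data.frame(metric = m, value = num / den, lo = ci[1], hi = ci[2],
               numerator = num, denominator = den, undefined = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$percent <- round_half_up(100 * out$value)
  out$percent_lo <- round_half_up(100 * out$lo)
  out$percent_hi <- round_half_up(100 * out$hi)
  structure(out, n = n, ci_method = ci_method, class = c("metrics_report",
                                                         "data.frame"))
}

#' Compare two algorithms' correctness by chi-square
#'
#' Pearson chi-square (no continuity correction, 1 df) on the 2x2 table
#' algorithm x {correct, incorrect}, where correct = tp + tn. Both
#' matrices must score gold standards of the same size. This treats the
#' two evaluations as independent samples and ignores item-level pairing
#' (the joint per-item distribution is not available from published
#' confusion matrices alone).
#'
#' @param cm_a,cm_b `confusion_matrix` objects for the two algorithms.
#' @return A list with `statistic`, `p_value`, and the correctness
#'   `table`.
#' @export
compare_algorithms <- function(cm_a, cm_b) {
  n_a <- cm_a$tp + cm_a$fp + cm_a$fn + cm_a$tn
  n_b <- cm_b$tp + cm_b$fp + cm_b$fn + cm_b$tn
  if (n_a != n_b) stop("both matrices must evaluate gold standards of equal size")
  correct <- c(cm_a$tp + cm_a$tn, cm_b$tp + cm_b$tn)
  obs <- rbind(a = c(correct[1], n_a - correct[1]),
               b = c(correct[2], n_b - correct[2]))
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expected == 0)) {
    stop("zero expected cell count; use an exact test instead")
  }
  stat <- sum((obs - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = obs)
}

#' Write an evaluation report (JSON + readable table)
#'
#' Mirrors the published confusion-matrix layout: cells, margins, and the
#' footnote metrics.
#'
#' @param report A `metrics_report`.
#' @param cm The `confusion_matrix` it was computed from.
#' @param path Output path for the JSON report; a `.txt` sibling holds the
#'   human-readable table.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, cm, path) {
  obj <- list(cells = list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn),
              margins = list(predicted_yes = cm$tp + cm$fp,
                             predicted_no = cm$fn + cm$tn,
                             gold_yes = cm$tp + cm$fn,
                             gold_no = cm$fp + cm$tn),
              n = attr(report, "n"), ci_method = attr(report, "ci_method"),
              metrics = report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt <- c(sprintf("n = %d outcomes", attr(report, "n")),
           "", "            gold yes   gold no",
           sprintf("pred yes  %9d %9d", cm$tp, cm$fp),
           sprintf("pred no   %9d %9d", cm$fn, cm$tn), "",
           sprintf("%-12s %3.0f%% (95%% CI %.0f-%.0f)", report$metric,
                   report$percent, report$percent_lo, report$percent_hi))
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics on n = %d (CI: %s)\n", attr(x, "n"),
              attr(x, "ci_method")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
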