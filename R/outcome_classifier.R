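## The trainable detector: balanced classes, a 61/12/27 stratified split,
## a hyperparameter grid, and accuracy-based model selection. The default
## desk-scale backend is a bag-of-words penalized logistic model
## ("text in, probability out"); a transformer encoder can implement the
## same contract but is deliberately not required.

#' Construct a labeled outcome corpus
#'
#' @param items Data.frame with `study_id`, `outcome_index`, `text`,
#'   `gold_label` (binary 0/1).
#' @return The validated data.frame (class `labeled_corpus`).
#' @export
labeled_corpus <- function(items) {
  req <- c("study_id", "outcome_index", "text", "gold_label")
  if (!all(req %in% names(items))) {
    stop("labeled corpus needs columns: ", paste(req, collapse = ", "))
  }
  key <- paste(items$study_id, items$outcome_index, sep = ":")
  if (anyDuplicated(key)) stop("outcome keys must be unique")
  items$gold_label <- as.integer(items$gold_label)
  class(items) <- c("labeled_corpus", "data.frame")
  items
}

#' Downsample the majority class to balance a corpus
#'
#' The majority class is randomly downsampled (without replacement) to the
#' minority-class size, giving exactly equal class counts.
#'
#' @param corpus A `labeled_corpus`.
#' @param seed Integer seed.
#' @return The balanced `labeled_corpus`.
#' @export
balance_classes <- function(corpus, seed = 1L) {
  counts <- table(factor(corpus$gold_label, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("both classes must be present to balance")
  m <- min(counts)
  set.seed(seed)
  keep <- unlist(lapply(c(0L, 1L), function(cl) {
    ix <- which(corpus$gold_label == cl)
    if (length(ix) > m) sort(sample(ix, m)) else ix
  }))
  out <- corpus[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Largest-remainder apportionment of n into parts proportional to ratios.
largest_remainder <- function(n, ratios) {
  q <- n * ratios / sum(ratios)
  sizes <- floor(q)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    ord <- order(-(q - sizes), seq_along(q))
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  as.integer(sizes)
}

#' Split a corpus into train / validation / test
#'
#' Sizes come from largest-remainder apportionment of the ratios (default
#' 61/12/27); explicit counts may be supplied instead via `sizes` (the
#' published split reports 2399/479/1065 of 3943, i.e. 60.8/12.1/27.0
#' percent, so exact counts are accepted as an alternative to ratios).
#' Assignment is a seeded shuffle stratified by label, keeping per-class
#' proportions within one item of the global ratios.
#'
#' @param corpus A `labeled_corpus`.
#' @param ratios Length-3 non-negative vector summing to 1 (tolerance 1e-9).
#' @param seed Integer seed.
#' @param sizes Optional explicit `c(train, validation, test)` counts
#'   summing to `nrow(corpus)`; overrides `ratios`.
#' @return A `dataset_split`: the corpus with a `subset` column plus
#'   `sizes`, `ratios`, `seed` attributes.
#' @export
split_corpus <- function(corpus, ratios = c(0.61, 0.12, 0.27), seed = 1L,
                         sizes = NULL) {
  n <- nrow(corpus)
  if (is.null(sizes)) {
    if (length(ratios) != 3L || any(ratios < 0) ||
        abs(sum(ratios) - 1) > 1e-9) {
      stop("ratios must be three non-negative numbers summing to 1")
    }
  } else {
    sizes <- as.integer(sizes)
    if (length(sizes) != 3L || any(sizes < 0) || sum(sizes) != n) {
      stop("explicit sizes must be three counts summing to nrow(corpus)")
    }
    ratios <- sizes / n
  }
  set.seed(seed)
  subset <- character(n)
  for (cl in unique(corpus$gold_label)) {
    ix <- which(corpus$gold_label == cl)
    cl_sizes <- largest_remainder(length(ix), ratios)
    subset[sample(ix)] <- rep(c("train", "validation", "test"), cl_sizes)
  }
  ## nudge per-class apportionment onto the requested global sizes
  target <- if (is.null(sizes)) largest_remainder(n, ratios) else sizes
  got <- c(sum(subset == "train"), sum(subset == "validation"),
           sum(subset == "test"))
  labs <- c("train", "validation", "test")
  while (any(got != target)) {
    from <- labs[which(got > target)[1]]
    to <- labs[which(got < target)[1]]
    ## move an item of the class most overrepresented in `from`, keeping
    ## per-class proportions within one item of the global ratios
    cand <- which(subset == from)
    excess <- vapply(cand, function(i) {
      cl_ix <- corpus$gold_label == corpus$gold_label[i]
      sum(subset[cl_ix] == from) -
        sum(cl_ix) * target[labs == from] / n
    }, numeric(1))
    subset[cand[which.max(excess)]] <- to
    got <- c(sum(subset == "train"), sum(subset == "validation"),
             sum(subset == "test"))
  }
  out <- corpus
  out$subset <- subset
  structure(out, sizes = structure(got, names = labs), ratios = ratios,
            seed = seed, class = c("dataset_split", class(corpus)))
}

## Tokenizer for the baseline backend: lowercase alphanumeric word tokens,
## truncated head-first at max_len tokens (keep the beginning).
classifier_tokens <- function(text, max_len = 512L) {
  toks <- regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))[[1]]
  if (length(toks) > max_len) toks <- toks[seq_len(max_len)]
  toks
}

build_dtm <- function(texts, vocab, max_len = 512L) {
  triplets <- lapply(seq_along(texts), function(i) {
    toks <- classifier_tokens(texts[i], max_len)
    toks <- toks[toks %in% names(vocab)]
    if (length(toks) == 0L) return(NULL)
    tab <- table(toks)
    cbind(i = i, j = unname(vocab[names(tab)]), x = as.integer(tab))
  })
  triplets <- do.call(rbind, triplets)
  if (is.null(triplets)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(texts), length(vocab))))
  }
  Matrix::sparseMatrix(i = triplets[, "i"], j = triplets[, "j"],
                       x = triplets[, "x"],
                       dims = c(length(texts), length(vocab)))
}

#' The default hyperparameter grid for the baseline backend
#'
#' Grid points are free-form hyperparameter lists; the baseline backend
#' reads `lambda` (ridge penalty) and `alpha` (elastic-net mixing).
#'
#' @return A list of hyperparameter settings.
#' @export
default_grid <- function() {
  list(list(lambda = 1e-2, alpha = 0),
       list(lambda = 1e-3, alpha = 0),
       list(lambda = 1e-4, alpha = 0))
}

fit_baseline <- function(x, y, hyper) {
  lambda <- hyper$lambda %||% 1e-3
  alpha <- hyper$alpha %||% 0
  fit <- glmnet::glmnet(x, factor(y, levels = c(0L, 1L)),
                        family = "binomial", alpha = alpha,
                        lambda = lambda * c(100, 10, 1),
                        standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = lambda))
  list(intercept = beta[1], coef = beta[-1])
}

score_baseline <- function(model, x) {
  as.numeric(stats::plogis(model$intercept + as.numeric(x %*% model$coef)))
}

binary_metrics <- function(pred, truth) {
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  acc <- mean(pred == truth)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(recall) && prec + recall > 0) {
    2 * prec * recall / (prec + recall)
  } else NA_real_
  c(accuracy = acc, recall = recall, f1 = f1)
}

#' Train the outcome classifier over a hyperparameter grid
#'
#' Fits one model per grid point on the training subset, evaluates
#' accuracy, recall and F1 on the validation subset, and returns the
#' accuracy-argmax model (ties break toward the earlier grid point — the
#' published procedure states accuracy-based selection but no tie rule).
#'
#' @param split A `dataset_split` with non-empty train and validation
#'   subsets.
#' @param backend Only `"baseline_bow"` is built in.
#' @param grid List of hyperparameter settings (see [default_grid()]).
#' @param max_sequence_length Token truncation length (default 512,
#'   head-first).
#' @return A `prom_classifier` with the fitted weights, the selection
#'   report (one row per grid point) and the selected index.
#' @export
train_classifier <- function(split, backend = "baseline_bow",
                             grid = default_grid(),
                             max_sequence_length = 512L) {
  stopifnot(inherits(split, "dataset_split"))
  if (!identical(backend, "baseline_bow")) {
    stop("unknown backend: ", backend,
         " (only 'baseline_bow' ships with the package)")
  }
  if (length(grid) == 0L) stop("hyperparameter grid must be non-empty")
  train <- split[split$subset == "train", , drop = FALSE]
  val <- split[split$subset == "validation", , drop = FALSE]
  if (nrow(train) == 0L) stop("training set is empty")
  if (nrow(val) == 0L) stop("validation set is empty")
  tokens <- unlist(lapply(train$text, classifier_tokens,
                          max_len = max_sequence_length))
  vocab_terms <- sort(unique(tokens))
  if (length(vocab_terms) < 2L) stop("training vocabulary is degenerate")
  vocab <- structure(seq_along(vocab_terms), names = vocab_terms)
  x_train <- build_dtm(train$text, vocab, max_sequence_length)
  x_val <- build_dtm(val$text, vocab, max_sequence_length)
  fits <- vector("list", length(grid))
  report <- data.frame()
  for (g in seq_along(grid)) {
    fits[[g]] <- fit_baseline(x_train, train$gold_label, grid[[g]])
    val_pred <- as.integer(score_baseline(fits[[g]], x_val) >= 0.5)
    m <- binary_metrics(val_pred, val$gold_label)
    report <- rbind(report, data.frame(
      grid_point = g,
      lambda = grid[[g]]$lambda %||% NA_real_,
      alpha = grid[[g]]$alpha %||% NA_real_,
      val_accuracy = m["accuracy"], val_recall = m["recall"],
      val_f1 = m["f1"], row.names = NULL))
  }
  best <- which.max(report$val_accuracy)  # which.max takes the first tie
  structure(list(backend_id = backend, vocab = vocab,
                 model = fits[[best]], hyperparameters = grid[[best]],
                 max_sequence_length = as.integer(max_sequence_length),
                 selection_metric = "accuracy", selected = best,
                 report = report),
            class = "prom_classifier")
}

#' Predict PROM/PREM presence for new texts
#'
#' One label and one score in `[0, 1]` per text; threshold 0.5;
#' deterministic given the model. Empty strings are valid input and score
#' at the model's intercept (the class prior).
#'
#' @param object A fitted `prom_classifier`.
#' @param texts Character vector of outcome texts.
#' @param ... Unused.
#' @return Data.frame with `label` (0/1) and `score`.
#' @export
predict.prom_classifier <- function(object, texts, ...) {
  if (is.null(object$model)) stop("model is not fitted")
  x <- build_dtm(texts, object$vocab, object$max_sequence_length)
  score <- score_baseline(object$model, x)
  data.frame(label = as.integer(score >= 0.5), score = score)
}

#' Save / load a classifier artifact directory
#'
#' The artifact is plain text: `manifest.json` (backend, hyperparameters,
#' selection report) and `weights.tsv` (term, coefficient; intercept under
#' the pseudo-term `(Intercept)`).
#'
#' @param model A `prom_classifier`.
#' @param dir Artifact directory.
#' @return `dir` (writer) or the reloaded `prom_classifier` (reader).
#' @export
write_classifier <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(backend_id = model$backend_id,
                   hyperparameters = model$hyperparameters,
                   max_sequence_length = model$max_sequence_length,
                   selection_metric = model$selection_metric,
                   selected = model$selected, report = model$report)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  w <- data.frame(term = c("(Intercept)", names(model$vocab)),
                  coef = c(model$model$intercept, model$model$coef))
  utils::write.table(w, file.path(dir, "weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  w <- utils::read.delim(file.path(dir, "weights.tsv"),
                         stringsAsFactors = FALSE)
  terms <- w$term[-1]
  structure(list(backend_id = manifest$backend_id,
                 vocab = structure(seq_along(terms), names = terms),
                 model = list(intercept = w$coef[1], coef = w$coef[-1]),
                 hyperparameters = manifest$hyperparameters,
                 max_sequence_length = manifest$max_sequence_length,
                 selection_metric = manifest$selection_metric,
                 selected = manifest$selected,
                 report = manifest$report),
            class = "prom_classifier")
}

#' @export
print.prom_classifier <- function(x, ...) {
  cat(sprintf("prom_classifier (%s): %d terms, grid point %d selected (val accuracy %.3f)\n",
              x$backend_id, length(x$vocab), x$selected,
              x$report$val_accuracy[x$selected]))
  invisible(x)
}
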