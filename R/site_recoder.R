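## Recoding free-text cancer-condition strings into homogeneous site
## labels: k-means over term-frequency vectors, top-word cluster naming,
## and a nearest-prototype ("few-shot") classifier.

## Histology-generic oncology words carry no site information; keeping
## them would let "cancer" vs "carcinoma" spelling decide clusters, so
## they are stopped alongside ordinary English function words.
ONCO_STOPWORDS <- c(
  "cancer", "cancers", "carcinoma", "carcinomas", "adenocarcinoma",
  "adenocarcinomas", "neoplasm", "neoplasms", "tumor", "tumors", "tumour",
  "tumours", "malignant", "malignancy", "malignancies", "metastatic",
  "metastasis", "metastases", "advanced", "stage", "recurrent",
  "refractory", "oncology", "carcinomatosis", "sarcoma", "disease",
  "patients", "cell")

#' The fixed stop-word list used for site recoding
#'
#' The English list is versioned in the package (`extdata/stopwords_en.txt`)
#' to keep top-word cluster naming reproducible; oncology histology-generic
#' words are appended so that site words, not histology words, drive the
#' clustering.
#'
#' @param include_domain Append the oncology-generic words (default TRUE).
#' @return Character vector of stop words.
#' @export
site_stopwords <- function(include_domain = TRUE) {
  en <- readLines(system.file("extdata", "stopwords_en.txt",
                              package = "promscan", mustWork = TRUE),
                  encoding = "UTF-8")
  if (include_domain) c(en, ONCO_STOPWORDS) else en
}

site_tokens <- function(x, stopwords) {
  toks <- regmatches(tolower(x), gregexpr("[a-z]+", tolower(x)))[[1]]
  toks[!(toks %in% stopwords)]
}

site_tf_matrix <- function(strings, stopwords, vocab = NULL) {
  token_list <- lapply(strings, site_tokens, stopwords = stopwords)
  if (is.null(vocab)) vocab <- sort(unique(unlist(token_list)))
  mat <- matrix(0, nrow = length(strings), ncol = length(vocab),
                dimnames = list(NULL, vocab))
  for (i in seq_along(token_list)) {
    tab <- table(token_list[[i]][token_list[[i]] %in% vocab])
    if (length(tab) > 0L) mat[i, names(tab)] <- as.numeric(tab)
  }
  mat
}

#' Cluster free-text cancer-site strings
#'
#' Strings are embedded as term-frequency vectors (lowercased, stop words
#' removed), clustered with seeded k-means, and each cluster is summarized
#' by its 10 most frequent words (its provisional name).
#'
#' @param condition_strings Character vector of condition strings.
#' @param k Number of clusters (`k >= 1`, at most the number of distinct
#'   strings).
#' @param seed Integer seed for the k-means initialization.
#' @param stopwords Stop-word list (default [site_stopwords()]).
#' @return A `site_cluster_model`: list with `k`, `clusters` (each holding
#'   `cluster_id`, `members`, `top_words`) and `assignment` (integer
#'   vector along `condition_strings`).
#' @export
cluster_sites <- function(condition_strings, k, seed = 1L,
                          stopwords = site_stopwords()) {
  stopifnot(k >= 1L)
  distinct <- unique(condition_strings)
  if (k > length(distinct)) {
    stop("k exceeds the number of distinct condition strings")
  }
  mat <- site_tf_matrix(distinct, stopwords)
  if (ncol(mat) == 0L) stop("no informative tokens after stop-word removal")
  set.seed(seed)
  km <- stats::kmeans(mat, centers = k, nstart = 10L, iter.max = 50L)
  assignment_distinct <- km$cluster
  clusters <- lapply(seq_len(k), function(cl) {
    members <- distinct[assignment_distinct == cl]
    counts <- colSums(mat[assignment_distinct == cl, , drop = FALSE])
    counts <- sort(counts[counts > 0], decreasing = TRUE)
    list(cluster_id = cl, members = members,
         top_words = utils::head(names(counts), 10L))
  })
  assignment <- assignment_distinct[match(condition_strings, distinct)]
  structure(list(k = k, clusters = clusters, assignment = assignment,
                 stopwords = stopwords),
            class = "site_cluster_model")
}

#' Build site prototypes from exemplar sentences
#'
#' @param exemplars Data.frame with `site_label` and `exemplar_text`
#'   columns (by convention eight exemplars per label).
#' @param stopwords Stop-word list.
#' @return A `site_prototypes` object: per-label term-frequency centroids.
#' @export
site_prototypes <- function(exemplars, stopwords = site_stopwords()) {
  stopifnot(nrow(exemplars) > 0L)
  vocab_mat <- site_tf_matrix(exemplars$exemplar_text, stopwords)
  labels <- sort(unique(exemplars$site_label))
  centroids <- t(vapply(labels, function(lb) {
    colMeans(vocab_mat[exemplars$site_label == lb, , drop = FALSE])
  }, numeric(ncol(vocab_mat))))
  rownames(centroids) <- labels
  structure(list(centroids = centroids, vocab = colnames(vocab_mat),
                 stopwords = stopwords),
            class = "site_prototypes")
}

#' Classify a condition string by nearest prototype
#'
#' Cosine similarity of the string's term-frequency vector against each
#' label's exemplar centroid; confidence is the winning similarity.
#' Strings sharing no vocabulary with any prototype (or empty strings)
#' fall back to `"unspecified"` under the minimum-confidence floor.
#'
#' @param condition_string A single condition string.
#' @param prototypes A `site_prototypes` object.
#' @param min_confidence Confidence floor below which `"unspecified"` is
#'   returned (default 0.1).
#' @return A list with `site_label` and `confidence`.
#' @export
classify_site <- function(condition_string, prototypes,
                          min_confidence = 0.1) {
  if (is.na(condition_string) || !nzchar(trimws(condition_string))) {
    return(list(site_label = "unspecified", confidence = 0))
  }
  v <- site_tf_matrix(condition_string, prototypes$stopwords,
                      vocab = prototypes$vocab)[1, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(list(site_label = "unspecified", confidence = 0))
  cen <- prototypes$centroids
  sims <- as.numeric(cen %*% v) /
    (sqrt(rowSums(cen^2)) * nv)
  sims[is.na(sims)] <- 0
  best <- which.max(sims)
  if (sims[best] < min_confidence) {
    return(list(site_label = "unspecified", confidence = unname(sims[best])))
  }
  list(site_label = rownames(cen)[best], confidence = unname(sims[best]))
}

#' Recode a vector of condition strings
#'
#' @param condition_strings Character vector.
#' @param prototypes A `site_prototypes` object.
#' @param min_confidence Passed to [classify_site()].
#' @return Data.frame `condition`, `site_label`, `confidence`.
#' @export
recode_sites <- function(condition_strings, prototypes,
                         min_confidence = 0.1) {
  res <- lapply(condition_strings, classify_site, prototypes = prototypes,
                min_confidence = min_confidence)
  data.frame(condition = condition_strings,
             site_label = vapply(res, `[[`, character(1), "site_label"),
             confidence = vapply(res, `[[`, numeric(1), "confidence"),
             stringsAsFactors = FALSE)
}

#' Read a prototype TSV (`site_label`, `exemplar_text`)
#'
#' @param path TSV path.
#' @param stopwords Stop-word list.
#' @return A `site_prototypes` object.
#' @export
read_site_prototypes <- function(path, stopwords = site_stopwords()) {
  site_prototypes(utils::read.delim(path, stringsAsFactors = FALSE),
                  stopwords = stopwords)
}

#' @export
print.site_cluster_model <- function(x, ...) {
  cat("site_cluster_model: k =", x$k, "\n")
  for (cl in x$clusters) {
    cat(sprintf("  cluster %d (%d members): %s\n", cl$cluster_id,
                length(cl$members),
                paste(utils::head(cl$top_words, 5), collapse = ", ")))
  }
  invisible(x)
}
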