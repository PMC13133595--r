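## Gold-standard annotation workflow: stratified subset sampling, paired
## blinded labels, Cohen's kappa, consensus adjudication.

#' Sample the labeling subset from matcher flags
#'
#' Draws a simple random sample without replacement of
#' `floor(pos_fraction * N_pos)` flagged-positive and
#' `floor(neg_fraction * N_neg)` flagged-negative outcomes (defaults 15%
#' and 2%, the published design). Reproducible given `seed`.
#'
#' @param flags Data.frame with `study_id`, `outcome_index`, `matched`
#'   (from [flag_corpus()]).
#' @param pos_fraction,neg_fraction Sampling fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data.frame of sampled keys (`study_id`, `outcome_index`,
#'   `matched`).
#' @export
sample_labeling_subset <- function(flags, pos_fraction = 0.15,
                                   neg_fraction = 0.02, seed = 1L) {
  if (pos_fraction < 0 || pos_fraction > 1 || neg_fraction < 0 ||
      neg_fraction > 1) {
    stop("sampling fractions must lie in [0, 1]")
  }
  pos <- which(flags$matched)
  neg <- which(!flags$matched)
  n_pos <- floor(pos_fraction * length(pos))
  n_neg <- floor(neg_fraction * length(neg))
  set.seed(seed)
  take <- sort(c(if (n_pos > 0L) sample(pos, n_pos),
                 if (n_neg > 0L) sample(neg, n_neg)))
  out <- flags[take, c("study_id", "outcome_index", "matched"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign sampled outcomes to annotator pairs
#'
#' Seeded round-robin partition of the sampled keys over `n_pairs`
#' annotator pairs (the published workflow used 16 experts in 8 pairs).
#'
#' @param keys Data.frame of outcome keys.
#' @param n_pairs Number of pairs.
#' @param seed Integer seed.
#' @return `keys` with an added `pair_id` column.
#' @export
assign_pairs <- function(keys, n_pairs = 8L, seed = 1L) {
  stopifnot(n_pairs >= 1L)
  set.seed(seed)
  ord <- sample.int(nrow(keys))
  pair <- integer(nrow(keys))
  pair[ord] <- rep_len(seq_len(n_pairs), nrow(keys))
  keys$pair_id <- sprintf("pair%02d", pair)
  keys
}

#' Cohen's kappa for two binary (or categorical) label vectors
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginal label distributions. When both
#' vectors are identical, 1 is returned even in the degenerate
#' single-category case where `p_e = 1`.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  if (length(labels_a) == 0L) stop("label vectors must be non-empty")
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  if (identical(a, b)) return(1)
  levels_all <- union(a, b)
  p_o <- mean(a == b)
  p_a <- table(factor(a, levels = levels_all)) / length(a)
  p_b <- table(factor(b, levels = levels_all)) / length(b)
  p_e <- sum(as.numeric(p_a) * as.numeric(p_b))
  (p_o - p_e) / (1 - p_e)
}

#' Adjudicate paired labels into a gold label set
#'
#' Agreements pass through unchanged; disagreements take the supplied
#' consensus resolution. The result is a complete gold label set with 100%
#' post-adjudication agreement.
#'
#' @param records Data.frame with `study_id`, `outcome_index`, `label_a`,
#'   `label_b` (binary 0/1 or logical), optional `pair_id`.
#' @param resolution Named vector mapping `"<study_id>:<outcome_index>"`
#'   keys to the consensus binary label, for every disagreement.
#' @return An object of class `gold_label_set`: the records with an
#'   `adjudicated_label` column plus `kappa` (overall, computed before
#'   adjudication) and `kappa_per_pair` when `pair_id` is present.
#' @export
adjudicate <- function(records, resolution = c()) {
  la <- as.integer(records$label_a)
  lb <- as.integer(records$label_b)
  keys <- paste(records$study_id, records$outcome_index, sep = ":")
  disagree <- which(la != lb)
  unresolved <- setdiff(keys[disagree], names(resolution))
  if (length(unresolved) > 0L) {
    stop("missing consensus resolution for: ",
         paste(unresolved, collapse = ", "))
  }
  adjudicated <- la
  adjudicated[disagree] <- as.integer(resolution[keys[disagree]])
  records$adjudicated_label <- adjudicated
  kappa_per_pair <- NULL
  if (!is.null(records$pair_id)) {
    kappa_per_pair <- vapply(split(seq_len(nrow(records)), records$pair_id),
                             function(ix) cohens_kappa(la[ix], lb[ix]),
                             numeric(1))
  }
  structure(list(records = records,
                 kappa = cohens_kappa(la, lb),
                 kappa_per_pair = kappa_per_pair),
            class = "gold_label_set")
}

#' Read blinded label files and merge them
#'
#' Blinding is structural: each annotator's labels live in a separate TSV
#' (`study_id`, `outcome_index`, `label` as yes/no or 0/1, `annotator_id`)
#' and are only merged here, at kappa/adjudication time.
#'
#' @param path_a,path_b The two annotators' label files.
#' @return Data.frame with `label_a` and `label_b` columns, one row per
#'   outcome key present in both files.
#' @export
read_label_pair <- function(path_a, path_b) {
  parse_one <- function(path, suffix) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    lab <- d$label
    if (is.character(lab)) lab <- as.integer(tolower(lab) %in% c("yes", "y", "1", "true"))
    d[[paste0("label_", suffix)]] <- as.integer(lab)
    d[, c("study_id", "outcome_index", paste0("label_", suffix))]
  }
  merge(parse_one(path_a, "a"), parse_one(path_b, "b"),
        by = c("study_id", "outcome_index"))
}

#' @export
print.gold_label_set <- function(x, ...) {
  cat("gold_label_set:", nrow(x$records), "records, pre-adjudication kappa =",
      round(x$kappa, 3), "\n")
  invisible(x)
}
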