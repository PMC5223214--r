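# Cross-validated evaluation of target prediction.
#
# Fivefold compound-split cross-validation: compounds in the gold-standard
# interactome are partitioned into folds; each fold's compound-protein pairs
# are scored against a model built from the remaining folds only (so a test
# compound never matches itself), and ROC-AUC / PR-AUC are computed on the
# pooled test pairs (per-fold metrics are also reported). Negatives are all
# compound-protein pairs absent from the gold standard (closed world).

#' Split compounds into cross-validation folds
#'
#' Random partition into `n_folds` subsets of roughly equal size (sizes
#' differ by at most one), reproducible given the seed. Only compounds are
#' split; proteins are common to all folds.
#'
#' @param compounds character vector.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return list of disjoint character vectors covering `compounds`.
#' @export
kfold_split <- function(compounds, n_folds = 5, seed = 1) {
  n <- length(compounds)
  if (n_folds < 2) abort("kfold_split: need n_folds >= 2")
  if (n < n_folds) abort("kfold_split: fewer compounds (%d) than folds (%d)", n, n_folds)
  shuffled <- with_seed(seed, sample(compounds))
  assignment <- sort(rep_len(seq_len(n_folds), n))
  unname(split(shuffled, assignment))
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted 1/2 (the rank-sum formulation). 1 is perfect
#' inference, 0.5 random.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("roc_auc: need at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) area from the ranked score list: precision is
#' evaluated at each distinct score threshold and integrated against the
#' recall increments. 1 is perfect inference; random scoring gives
#' approximately the positive fraction.
#'
#' @inheritParams roc_auc
#' @return AUPR in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0L) abort("pr_auc: need at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  # evaluate at the last index of each tied-score block
  at <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- tp[at]
  fp <- fp[at]
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

# prediction-score matrix (queries x proteins) from a precomputed
# compound-level similarity matrix, taking per protein the max over binders
score_matrix_from_sim <- function(sim_score, queries, interactome, refs) {
  proteins <- interactome$proteins
  out <- matrix(NA_real_, length(queries), length(proteins),
                dimnames = list(queries, proteins))
  for (p in proteins) {
    binders <- intersect(binders_of(interactome, p), refs)
    if (!length(binders)) next
    sub <- sim_score[queries, binders, drop = FALSE]
    out[, p] <- apply(sub, 1L, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  }
  out
}

#' Fivefold compound-split cross-validation of target prediction
#'
#' @param gold an `interactome_table`: the gold-standard compound-protein
#'   pairs (labels and reference model).
#' @param set a `signature_set` with the compounds' signatures.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the compound split.
#' @param strategy similarity strategy (`"same"`, `"different"`, `"all"`).
#' @param protocol `"common"` evaluates only gold compounds that have
#'   non-degenerate signatures; `"merged"` evaluates all gold compounds and
#'   sets the scores of compounds lacking expression data to zero.
#' @param missing_fill numeric fill for undefined similarities when pooling
#'   (default 0).
#' @return object of class `cv_result`: `$pairs` (compound, protein, score,
#'   label, fold), `$pooled` (AUC, AUPR), `$per_fold`, `$config`.
#' @export
run_cv <- function(gold, set, n_folds = 5, seed = 1,
                   strategy = c("same", "different", "all"),
                   protocol = c("common", "merged"), missing_fill = 0) {
  strategy <- match.arg(strategy)
  protocol <- match.arg(protocol)
  have_sig <- unique(set$keys$compound_id[!set$keys$degenerate])
  gold_cpds <- gold$compounds
  eval_cpds <- if (protocol == "common") intersect(gold_cpds, have_sig) else gold_cpds
  if (length(eval_cpds) < n_folds) abort("run_cv: not enough evaluable compounds for %d folds", n_folds)
  folds <- kfold_split(sort(eval_cpds), n_folds, seed)

  sig_cpds <- intersect(eval_cpds, have_sig)
  sub <- subset_signature_set(set, sig_cpds)
  sim <- compound_similarity_matrix(sub, sub, strategy)

  proteins <- gold$proteins
  label_key <- paste(gold$pairs$compound_id, gold$pairs$protein_id, sep = "\r")
  pairs <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- folds[[f]]
    train <- setdiff(eval_cpds, test)
    train_refs <- intersect(train, sig_cpds)
    test_sig <- intersect(test, sig_cpds)
    scores <- matrix(missing_fill, length(test), length(proteins),
                     dimnames = list(test, proteins))
    if (length(test_sig) && length(train_refs)) {
      sm <- score_matrix_from_sim(sim$score, test_sig, gold, train_refs)
      sm[is.na(sm)] <- missing_fill
      scores[test_sig, ] <- sm
    }
    df <- data.frame(compound = rep(test, times = length(proteins)),
                     protein = rep(proteins, each = length(test)),
                     score = as.vector(scores),
                     fold = f, stringsAsFactors = FALSE)
    df$label <- as.integer(paste(df$compound, df$protein, sep = "\r") %in% label_key)
    pairs[[f]] <- df
  }
  pairs <- do.call(rbind, pairs)
  per_fold <- do.call(rbind, lapply(seq_len(n_folds), function(f) {
    p <- pairs[pairs$fold == f, ]
    data.frame(fold = f, auc = roc_auc(p$score, p$label), aupr = pr_auc(p$score, p$label))
  }))
  structure(list(pairs = pairs,
                 pooled = c(auc = roc_auc(pairs$score, pairs$label),
                            aupr = pr_auc(pairs$score, pairs$label)),
                 per_fold = per_fold,
                 config = list(n_folds = n_folds, seed = seed, strategy = strategy,
                               protocol = protocol, missing_fill = missing_fill)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold, strategy=%s, protocol=%s\n",
              x$config$n_folds, x$config$strategy, x$config$protocol))
  cat(sprintf("  pooled AUC  = %.4f\n  pooled AUPR = %.4f\n",
              x$pooled["auc"], x$pooled["aupr"]))
  invisible(x)
}
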