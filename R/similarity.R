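# Transcriptional and chemical similarity.
#
# Transcriptional similarity between two compounds is the Pearson correlation
# of their signatures, maximized over cell-line pairings under one of three
# strategies: same cell line-matching (max over cell lines shared by both
# compounds), different cell line-matching (max over ordered cross-cell
# pairs), and all cell line-matching (max of the two). When no admissible
# pairing exists the score is undefined and returned as NA; callers treat NA
# as "no evidence" and, where a complete numeric matrix is required, fill 0.

#' Pearson correlation with an undefined sentinel
#'
#' Standard product-moment correlation; a constant vector has no correlation
#' and yields `NA` (callers skip such profiles) rather than an error.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
pearson_similarity <- function(x, y) {
  if (length(x) != length(y)) abort("pearson_similarity: length mismatch")
  if (length(x) < 2L) abort("pearson_similarity: need length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# max over an index set of a correlation matrix, with lexicographic
# tie-breaking on (query cell, ref cell); returns score + argmax cells
max_over_pairs <- function(C, qcells, rcells, pairs) {
  if (!nrow(pairs)) return(list(score = NA_real_, query_cell = NA_character_, ref_cell = NA_character_))
  vals <- C[cbind(pairs[, 1L], pairs[, 2L])]
  ok <- !is.na(vals)
  if (!any(ok)) return(list(score = NA_real_, query_cell = NA_character_, ref_cell = NA_character_))
  vals <- vals[ok]
  pairs <- pairs[ok, , drop = FALSE]
  best <- max(vals)
  cand <- which(vals == best)
  o <- order(qcells[pairs[cand, 1L]], rcells[pairs[cand, 2L]])
  pick <- cand[o[1L]]
  list(score = best, query_cell = qcells[pairs[pick, 1L]], ref_cell = rcells[pairs[pick, 2L]])
}

#' Cell-line-matched transcriptional similarity between two compounds
#'
#' @param query,ref genes-by-cells signature matrices for the two compounds
#'   (cell lines as column names), e.g. from [signature_group()].
#' @param strategy `"same"` (max Pearson over cell lines present in both),
#'   `"different"` (max over ordered pairs of distinct cell lines), or
#'   `"all"` (max of the two; defined if either is).
#' @return list with `score` (`NA` when undefined), `query_cell`, `ref_cell`
#'   (the argmax pairing; ties go to the lexicographically smallest cells).
#' @export
compound_similarity <- function(query, ref, strategy = c("same", "different", "all")) {
  strategy <- match.arg(strategy)
  if (!ncol(query) || !ncol(ref)) {
    return(list(score = NA_real_, query_cell = NA_character_, ref_cell = NA_character_))
  }
  C <- suppressWarnings(stats::cor(query, ref))
  C[!is.finite(C)] <- NA_real_
  qcells <- colnames(query)
  rcells <- colnames(ref)
  grid <- as.matrix(expand.grid(q = seq_along(qcells), r = seq_along(rcells)))
  same_pairs <- grid[qcells[grid[, 1L]] == rcells[grid[, 2L]], , drop = FALSE]
  diff_pairs <- grid[qcells[grid[, 1L]] != rcells[grid[, 2L]], , drop = FALSE]
  switch(strategy,
         same = max_over_pairs(C, qcells, rcells, same_pairs),
         different = max_over_pairs(C, qcells, rcells, diff_pairs),
         all = {
           s <- max_over_pairs(C, qcells, rcells, same_pairs)
           d <- max_over_pairs(C, qcells, rcells, diff_pairs)
           if (is.na(s$score)) d
           else if (is.na(d$score)) s
           else if (d$score > s$score) d else s
         })
}

#' @rdname compound_similarity
#' @export
similarity_same_cell <- function(query, ref) compound_similarity(query, ref, "same")

#' @rdname compound_similarity
#' @export
similarity_different_cell <- function(query, ref) compound_similarity(query, ref, "different")

#' @rdname compound_similarity
#' @export
similarity_all_cell <- function(query, ref) compound_similarity(query, ref, "all")

#' All-pairs compound similarity matrix
#'
#' Computes strategy similarity between every query compound and every
#' reference compound in one pass, sharing a single signature cross
#' correlation. Degenerate signatures are excluded from all maxima.
#'
#' @param query_set,ref_set `signature_set` objects sharing gene order
#'   (`ref_set` defaults to `query_set`).
#' @param strategy similarity strategy, see [compound_similarity()].
#' @return list of matrices (`score`, `query_cell`, `ref_cell`) with query
#'   compounds as rows and reference compounds as columns; `score` is `NA`
#'   where undefined.
#' @export
compound_similarity_matrix <- function(query_set, ref_set = query_set,
                                       strategy = c("same", "different", "all")) {
  strategy <- match.arg(strategy)
  if (!identical(query_set$gene_ids, ref_set$gene_ids)) {
    abort("compound_similarity_matrix: gene universes differ")
  }
  qk <- query_set$keys[!query_set$keys$degenerate, , drop = FALSE]
  rk <- ref_set$keys[!ref_set$keys$degenerate, , drop = FALSE]
  qcmp <- sort(unique(query_set$keys$compound_id))
  rcmp <- sort(unique(ref_set$keys$compound_id))
  score <- matrix(NA_real_, length(qcmp), length(rcmp), dimnames = list(qcmp, rcmp))
  qcell <- matrix(NA_character_, length(qcmp), length(rcmp), dimnames = list(qcmp, rcmp))
  rcell <- matrix(NA_character_, length(qcmp), length(rcmp), dimnames = list(qcmp, rcmp))
  if (!nrow(qk) || !nrow(rk)) {
    return(list(score = score, query_cell = qcell, ref_cell = rcell))
  }
  qv <- query_set$values[, !query_set$keys$degenerate, drop = FALSE]
  rv <- ref_set$values[, !ref_set$keys$degenerate, drop = FALSE]
  C <- suppressWarnings(stats::cor(qv, rv))
  C[!is.finite(C)] <- NA_real_
  qidx <- split(seq_len(nrow(qk)), qk$compound_id)
  ridx <- split(seq_len(nrow(rk)), rk$compound_id)
  for (qc in names(qidx)) {
    qi <- qidx[[qc]]
    qcl <- qk$cell_line[qi]
    for (rc in names(ridx)) {
      ri <- ridx[[rc]]
      rcl <- rk$cell_line[ri]
      grid <- as.matrix(expand.grid(a = seq_along(qi), b = seq_along(ri)))
      is_same <- qcl[grid[, 1L]] == rcl[grid[, 2L]]
      pairs <- switch(strategy,
                      same = grid[is_same, , drop = FALSE],
                      different = grid[!is_same, , drop = FALSE],
                      all = grid)
      sub <- C[qi, ri, drop = FALSE]
      res <- max_over_pairs(sub, qcl, rcl, pairs)
      score[qc, rc] <- res$score
      qcell[qc, rc] <- res$query_cell
      rcell[qc, rc] <- res$ref_cell
    }
  }
  list(score = score, query_cell = qcell, ref_cell = rcell)
}

#' Generalized Jaccard similarity of feature-count vectors
#'
#' `sum(min(u_f, v_f)) / sum(max(u_f, v_f))` over the union of features;
#' reduces to the Tanimoto coefficient on binary vectors. Absent features
#' count as zero. Two all-zero vectors have no defined similarity.
#'
#' @param u,v named non-negative count vectors (sparse: absent = 0).
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' generalized_jaccard(c(f1 = 1, f2 = 2), c(f1 = 2, f2 = 1, f3 = 1))  # 2/5
generalized_jaccard <- function(u, v) {
  if (any(u < 0) || any(v < 0)) abort("generalized_jaccard: counts must be non-negative")
  feats <- union(names(u), names(v))
  if (!length(feats)) abort("generalized_jaccard: both vectors are empty")
  a <- b <- stats::setNames(numeric(length(feats)), feats)
  a[names(u)] <- u
  b[names(v)] <- v
  denom <- sum(pmax(a, b))
  if (denom == 0) abort("generalized_jaccard: both vectors are all-zero")
  sum(pmin(a, b)) / denom
}

#' Hierarchical clustering of control profiles
#'
#' QC utility: clusters control expression profiles (or per-cell-line
#' averaged profiles) with distance `1 - Pearson` and average linkage.
#' Constant profiles carry no correlation and are excluded with a warning.
#'
#' @param controls genes-by-profiles matrix of control expression profiles.
#' @param cell_lines character vector of cell-line labels, one per profile.
#' @param mode `"per-profile"` (one leaf per control profile) or
#'   `"averaged"` (profiles averaged within cell line first; one leaf per
#'   cell line).
#' @return an `hclust` tree; leaf labels are profile ids (tagged with the
#'   cell line as `cell:profile`) or cell-line names in averaged mode.
#' @export
cluster_controls <- function(controls, cell_lines, mode = c("per-profile", "averaged")) {
  mode <- match.arg(mode)
  stopifnot(ncol(controls) == length(cell_lines))
  if (mode == "averaged") {
    cells <- sort(unique(cell_lines))
    controls <- vapply(cells, function(cl) rowMeans(controls[, cell_lines == cl, drop = FALSE]),
                       numeric(nrow(controls)))
    colnames(controls) <- cells
  } else {
    colnames(controls) <- paste(cell_lines, colnames(controls) %||% seq_len(ncol(controls)),
                                sep = ":")
  }
  const <- apply(controls, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sprintf("excluding %d constant control profile(s) from clustering", sum(const)))
    controls <- controls[, !const, drop = FALSE]
  }
  if (ncol(controls) < 2L) abort("cluster_controls: need >= 2 non-constant profiles")
  d <- stats::as.dist(1 - stats::cor(controls))
  stats::hclust(d, method = "average")
}
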