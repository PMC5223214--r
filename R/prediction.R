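# Nearest-neighbor target-protein and therapeutic-indication prediction.
#
# For a query compound, the prediction score for protein k is the highest
# strategy similarity between the query and any interactome compound known
# to bind protein k; the best-matching compound and cell-line pairing are
# recorded as provenance. Indications transfer from similar interactome
# compounds that share predicted targets with the query. Every reported
# score is a realized pairwise similarity — never an interpolation.

#' Score candidate target proteins for query compounds
#'
#' For each query compound and each interactome protein, the score is the
#' maximum strategy similarity between the query and the protein's known
#' binders that have comparable signatures. Proteins whose binders all lack
#' a comparable signature get an undefined (`NA`) score. Ties among equally
#' similar best-match compounds are broken lexicographically for provenance
#' (the score is unaffected). The query itself is *not* excluded when it is
#' an interactome compound (its own targets then score 1 by self-similarity);
#' cross-validation must and does exclude self-matches via
#' `exclude_compounds`.
#'
#' @param set `signature_set` holding query and reference signatures.
#' @param queries character vector of query compound ids (must have
#'   signatures); default: all compounds in `set`.
#' @param interactome an `interactome_table` (the gold-standard
#'   compound-protein pairs).
#' @param strategy `"same"`, `"different"` or `"all"` cell line-matching.
#' @param exclude_compounds interactome compounds to ignore as references
#'   (e.g. the test fold in cross-validation).
#' @return data.frame of class `prediction_scores` with columns
#'   `query_compound`, `target`, `score`, `best_match_compound`,
#'   `best_match_cell_line` (formatted `querycell|refcell`).
#' @export
score_targets <- function(set, queries = NULL, interactome,
                          strategy = c("same", "different", "all"),
                          exclude_compounds = character()) {
  strategy <- match.arg(strategy)
  have_sig <- unique(set$keys$compound_id[!set$keys$degenerate])
  queries <- queries %||% sort(have_sig)
  missing <- setdiff(queries, set$keys$compound_id)
  if (length(missing)) abort("query compound '%s' has no signatures", missing[1L])
  refs <- setdiff(intersect(interactome$compounds, have_sig), exclude_compounds)
  if (!length(interactome$compounds)) abort("score_targets: empty interactome")

  qset <- subset_signature_set(set, queries)
  proteins <- interactome$proteins
  if (!length(refs)) {
    out <- expand.grid(target = proteins, query_compound = queries,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
    out$score <- NA_real_
    out$best_match_compound <- NA_character_
    out$best_match_cell_line <- NA_character_
    class(out) <- c("prediction_scores", "data.frame")
    return(out)
  }
  rset <- subset_signature_set(set, refs)
  sim <- compound_similarity_matrix(qset, rset, strategy)

  rows <- vector("list", length(queries) * length(proteins))
  n <- 0L
  for (q in queries) {
    for (p in proteins) {
      binders <- intersect(binders_of(interactome, p), refs)
      n <- n + 1L
      if (!length(binders)) {
        rows[[n]] <- data.frame(query_compound = q, target = p, score = NA_real_,
                                best_match_compound = NA_character_,
                                best_match_cell_line = NA_character_,
                                stringsAsFactors = FALSE)
        next
      }
      s <- sim$score[q, binders]
      if (all(is.na(s))) {
        rows[[n]] <- data.frame(query_compound = q, target = p, score = NA_real_,
                                best_match_compound = NA_character_,
                                best_match_cell_line = NA_character_,
                                stringsAsFactors = FALSE)
        next
      }
      best <- max(s, na.rm = TRUE)
      bm <- sort(binders[!is.na(s) & s == best])[1L]
      rows[[n]] <- data.frame(query_compound = q, target = p, score = best,
                              best_match_compound = bm,
                              best_match_cell_line = paste(sim$query_cell[q, bm],
                                                           sim$ref_cell[q, bm], sep = "|"),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("prediction_scores", "data.frame")
  out
}

subset_signature_set <- function(set, compounds) {
  sel <- set$keys$compound_id %in% compounds
  signature_set(set$values[, sel, drop = FALSE], set$keys[sel, , drop = FALSE])
}

#' Threshold prediction scores at an upper percentile
#'
#' Keeps pairs whose score reaches the upper `100 - percentile` tail of the
#' pooled defined-score distribution of the current run (nearest-rank
#' convention: the cutoff is the `ceiling(q * n)`-th largest defined score,
#' `q = (100 - percentile)/100`; ties at the cutoff are included). Known
#' (training) pairs can be excluded so the result is the set of *new*
#' predictions.
#'
#' @param scores `prediction_scores` data.frame.
#' @param percentile percentile in (0, 100); the default 95 keeps the upper
#'   5th percentile.
#' @param known optional `interactome_table` or `indication_table` of known
#'   pairs to exclude from the result.
#' @return subset of `scores` above the cutoff, with attribute `cutoff`.
#' @export
threshold_percentile <- function(scores, percentile = 95, known = NULL) {
  if (percentile <= 0 || percentile >= 100) abort("percentile must be in (0, 100)")
  defined <- scores$score[!is.na(scores$score)]
  if (!length(defined)) {
    warning("all scores undefined; returning an empty prediction set")
    out <- scores[0L, , drop = FALSE]
    attr(out, "cutoff") <- NA_real_
    return(out)
  }
  q <- (100 - percentile) / 100
  kth <- ceiling(q * length(defined))
  cutoff <- sort(defined, decreasing = TRUE)[kth]
  keep <- !is.na(scores$score) & scores$score >= cutoff
  out <- scores[keep, , drop = FALSE]
  if (!is.null(known)) {
    kp <- known$pairs
    known_key <- paste(kp[[1L]], kp[[2L]], sep = "\r")
    out <- out[!(paste(out$query_compound, out$target, sep = "\r") %in% known_key), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Transfer therapeutic indications from similar compounds
#'
#' A disease is predicted for the query when some interactome compound (a)
#' has that disease as a known indication and (b) shares at least one target
#' protein with the query's predicted-target set at the current threshold.
#' The transferred score is the target-prediction score realized through the
#' most similar qualifying compound (maximum over its known targets inside
#' the predicted set), so indication scores are always a subset of the
#' target-prediction scores.
#'
#' @param query query compound id.
#' @param target_scores `prediction_scores` for the query (with provenance).
#' @param predicted_targets character vector of proteins predicted for the
#'   query (e.g. from [threshold_percentile()]).
#' @param interactome an `interactome_table`.
#' @param indications an `indication_table`.
#' @return `prediction_scores` data.frame over diseases (empty if the
#'   indication table is empty or nothing qualifies).
#' @export
predict_indications <- function(query, target_scores, predicted_targets,
                                interactome, indications) {
  ts <- target_scores[target_scores$query_compound == query, , drop = FALSE]
  empty <- data.frame(query_compound = character(), target = character(),
                      score = numeric(), best_match_compound = character(),
                      best_match_cell_line = character(), stringsAsFactors = FALSE)
  class(empty) <- c("prediction_scores", "data.frame")
  if (!nrow(indications$pairs) || !length(predicted_targets)) return(empty)

  # per qualifying compound: best realized target-prediction score over its
  # known targets inside the predicted set
  assoc_score <- function(cpd) {
    shared <- intersect(targets_of(interactome, cpd), predicted_targets)
    if (!length(shared)) return(NULL)
    s <- ts[ts$target %in% shared & !is.na(ts$score), , drop = FALSE]
    if (!nrow(s)) return(NULL)
    s[order(-s$score, s$target), ][1L, ]
  }
  diseases <- sort(unique(indications$pairs$disease_id))
  rows <- lapply(diseases, function(dz) {
    cands <- sort(unique(indications$pairs$compound_id[indications$pairs$disease_id == dz]))
    cands <- setdiff(cands, query)
    scored <- lapply(cands, assoc_score)
    ok <- !vapply(scored, is.null, logical(1L))
    if (!any(ok)) return(NULL)
    cands <- cands[ok]
    scored <- scored[ok]
    vals <- vapply(scored, function(s) s$score, numeric(1L))
    pick <- which(vals == max(vals))[1L]  # cands sorted, ties -> lexicographic
    best <- scored[[pick]]
    data.frame(query_compound = query, target = dz, score = best$score,
               best_match_compound = cands[pick],
               best_match_cell_line = best$best_match_cell_line,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prediction_scores", "data.frame")
  out
}

#' Drug repositioning moves between disease chapters
#'
#' Counts, for every drug with at least one known indication, moves from the
#' drug's original ICD chapter to the chapters of its newly predicted
#' diseases (known diseases are excluded from "new"). The original chapter
#' is the chapter of the drug's lexicographically first known indication, so
#' the matrix total equals the number of (drug, new chapter) pairs. Diseases
#' without a chapter mapping are bucketed as `"unknown"`.
#'
#' @param predicted `prediction_scores` over diseases (possibly thresholded),
#'   for any number of drugs.
#' @param known an `indication_table` of known drug-disease associations.
#' @return square integer matrix, original chapters x new chapters.
#' @export
repositioning_matrix <- function(predicted, known) {
  chap <- function(dz) {
    ch <- known$chapters[dz]
    ifelse(is.na(ch), "unknown", ch)
  }
  drugs <- sort(unique(predicted$query_compound))
  moves <- list()
  for (drug in drugs) {
    known_dz <- sort(known$pairs$disease_id[known$pairs$compound_id == drug])
    if (!length(known_dz)) next
    origin <- chap(known_dz[1L])
    new_dz <- setdiff(predicted$target[predicted$query_compound == drug], known_dz)
    new_ch <- unique(chap(new_dz))
    for (ch in new_ch) moves[[length(moves) + 1L]] <- c(origin, ch)
  }
  labels <- sort(unique(c(vapply(moves, `[[`, character(1L), 1L),
                          vapply(moves, `[[`, character(1L), 2L),
                          unname(chap(unique(known$pairs$disease_id))))))
  m <- matrix(0L, length(labels), length(labels), dimnames = list(labels, labels))
  for (mv in moves) m[mv[1L], mv[2L]] <- m[mv[1L], mv[2L]] + 1L
  m
}
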