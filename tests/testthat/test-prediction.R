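# Nearest-neighbor target scoring, percentile thresholding, indication
# transfer, and repositioning bookkeeping.

test_that("target scores are maxima over binders with provenance", {
  fx <- small_fixture()
  it <- fx$ds$interactome
  scores <- score_targets(fx$set, interactome = it, strategy = "same")
  sim <- compound_similarity_matrix(fx$set, fx$set, "same")

  # every reported score is a realized pairwise similarity, exactly
  for (i in with_seed(9, sample(seq_len(nrow(scores)), 50))) {
    row <- scores[i, ]
    binders <- binders_of(it, row$target)
    if (is.na(row$score)) next
    expected <- max(sim$score[row$query_compound, binders], na.rm = TRUE)
    expect_equal(row$score, expected, tolerance = 1e-12)
    expect_true(row$best_match_compound %in% binders)
  }

  # self-match: a query in the interactome scores 1 for each of its targets
  q <- it$compounds[1]
  own <- scores[scores$query_compound == q & scores$target %in% targets_of(it, q), ]
  expect_true(all(abs(own$score - 1) < 1e-12))
  expect_true(all(own$best_match_compound == q))

  # excluding the query removes the self-match
  ex <- score_targets(fx$set, queries = q, interactome = it, strategy = "same",
                      exclude_compounds = q)
  own_ex <- ex[ex$target %in% targets_of(it, q), ]
  expect_true(all(is.na(own_ex$score) | own_ex$score < 1 - 1e-9))
  expect_true(all(own_ex$best_match_compound != q, na.rm = TRUE))
})

test_that("undefined similarities propagate as NA sentinels", {
  # two compounds profiled in disjoint cell sets: same-cell has no evidence
  genes <- paste0("g", 1:50)
  vals <- with_seed(1, matrix(stats::rnorm(100), 50, 2,
                              dimnames = list(genes, c("q|A", "r|B"))))
  keys <- data.frame(compound_id = c("q", "r"), cell_line = c("A", "B"),
                     time_h = 6, n_source_profiles = 1L, degenerate = FALSE)
  set <- signature_set(vals, keys)
  it <- interactome_table(data.frame(compound_id = "r", protein_id = "P1"))
  res <- score_targets(set, queries = "q", interactome = it, strategy = "same")
  expect_true(is.na(res$score))
  res_d <- score_targets(set, queries = "q", interactome = it, strategy = "different")
  expect_false(is.na(res_d$score))
})

test_that("percentile thresholding follows the nearest-rank convention", {
  mk <- function(s) {
    data.frame(query_compound = sprintf("c%03d", seq_along(s)), target = "P1",
               score = s, best_match_compound = "x", best_match_cell_line = "A|A")
  }
  kept <- threshold_percentile(mk(1:100), 95)
  expect_identical(sort(kept$score), 96:100)  # upper 5th percentile = 5 largest

  expect_identical(nrow(threshold_percentile(mk(1:100), 0.001)), 100L)
  expect_identical(nrow(threshold_percentile(mk(rep(2, 10)), 95)), 10L)  # all tied

  # monotone: raising the percentile never adds pairs
  s <- with_seed(2, stats::rnorm(200))
  sizes <- vapply(c(50, 80, 95, 99), function(p) nrow(threshold_percentile(mk(s), p)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))

  # known pairs drop out of the new-prediction set
  known <- interactome_table(data.frame(compound_id = "c100", protein_id = "P1"))
  kept2 <- threshold_percentile(mk(1:100), 95, known = known)
  expect_false("c100" %in% kept2$query_compound)

  allna <- mk(rep(NA_real_, 3))
  expect_warning(out <- threshold_percentile(allna, 95), "undefined")
  expect_identical(nrow(out), 0L)
})

test_that("indication transfer requires a shared predicted target", {
  it <- interactome_table(data.frame(compound_id = c("A", "B"),
                                     protein_id = c("P1", "P2")))
  ind <- indication_table(data.frame(compound_id = c("A", "B"),
                                     disease_id = c("D1", "D2")),
                          chapters = c(D1 = "I", D2 = "II"))
  ts <- data.frame(query_compound = "q", target = c("P1", "P2"),
                   score = c(0.8, 0.3), best_match_compound = c("A", "B"),
                   best_match_cell_line = c("A1|A1", "A1|A1"))
  # P1 predicted: A qualifies for D1 with the P1 score
  res <- predict_indications("q", ts, "P1", it, ind)
  expect_identical(res$target, "D1")
  expect_equal(res$score, 0.8)
  expect_identical(res$best_match_compound, "A")

  # B has an indication but no shared predicted target: no transfer
  expect_false("D2" %in% res$target)

  # two qualifying compounds: the higher associated score wins
  it2 <- interactome_table(data.frame(compound_id = c("A", "B"), protein_id = "P1"))
  ind2 <- indication_table(data.frame(compound_id = c("A", "B"), disease_id = "D1"))
  ts2 <- transform(ts, score = c(0.9, 0.3))
  res2 <- predict_indications("q", ts2, "P1", it2, ind2)
  expect_equal(res2$score, 0.9)

  # transferred scores are a subset of target-prediction scores
  expect_true(all(res2$score %in% ts2$score))

  empty <- predict_indications("q", ts, "P1", it,
                               indication_table(data.frame(compound_id = character(),
                                                           disease_id = character())))
  expect_identical(nrow(empty), 0L)
})

test_that("repositioning counts moves between chapters exactly once per drug", {
  known <- indication_table(data.frame(compound_id = c("d1", "d2"),
                                       disease_id = c("D1", "D2")),
                            chapters = c(D1 = "I", D2 = "II", D3 = "II", D4 = "unknownless"))
  predicted <- data.frame(query_compound = c("d1", "d1", "d2"),
                          target = c("D3", "D1", "Dx"),  # D1 already known, Dx unmapped
                          score = 0.5, best_match_compound = "z",
                          best_match_cell_line = "A|A")
  m <- repositioning_matrix(predicted, known)
  expect_identical(m["I", "II"], 1L)         # d1: chapter I -> II via D3
  expect_identical(m["II", "unknown"], 1L)   # d2: unmapped disease bucketed
  expect_identical(sum(m), 2L)               # total = number of (drug, new chapter) pairs

  none <- repositioning_matrix(predicted[0, ], known)
  expect_identical(sum(none), 0L)
})
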