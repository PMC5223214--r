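# Signature construction: standardization, the two normalizations,
# averaging, time collapsing, top/bottom selection, and orchestration.

test_that("standardize centers and scales with the population sd", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(s^2)), 1, tolerance = 1e-12)

  z <- standardize(c(5, 5, 5))
  expect_identical(as.numeric(z), c(0, 0, 0))
  expect_true(attr(z, "degenerate"))

  expect_error(standardize(c(1, NA, 2)), "non-finite")

  for (seed in 1:5) {
    v <- with_seed(seed, stats::rnorm(50, sd = 3))
    expect_equal(as.numeric(standardize(standardize(v))), as.numeric(standardize(v)),
                 tolerance = 1e-12)
  }
})

test_that("biological-control signatures are standardized log ratios", {
  s <- signature_biological_control(c(2, 4, 8), c(2, 2, 2), log_base = 2)
  expect_equal(as.numeric(s), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)

  same <- signature_biological_control(c(3, 3), c(3, 3))
  expect_true(attr(same, "degenerate"))

  floored <- signature_biological_control(c(1, 2, 4), c(0, 1, 1), epsilon = 0.01)
  expect_true(all(is.finite(floored)))

  expect_error(signature_biological_control(1:3, 1:4), "length")
})

test_that("mean-centering uses the averaged control profile", {
  grp <- cbind(a = c(2, 4), b = c(4, 2))
  s <- signature_mean_centering(grp, target = c(2, 4), log_base = 2)
  expect_equal(as.numeric(s), c(-1, 1), tolerance = 1e-9)

  # order of profiles in the group is immaterial
  s2 <- signature_mean_centering(grp[, c(2, 1)], target = c(2, 4), log_base = 2)
  expect_equal(as.numeric(s2), as.numeric(s), tolerance = 1e-12)

  ident <- signature_mean_centering(cbind(c(1, 2), c(1, 2)), target = c(1, 2))
  expect_true(attr(ident, "degenerate"))

  expect_error(signature_mean_centering(cbind(c(1, 2)), target = c(1, 2)), ">= 2")
})

test_that("averaging integrates replicates and re-standardizes", {
  v <- standardize(c(1, 5, 2, 7))
  expect_equal(as.numeric(average_signatures(list(v))), as.numeric(v), tolerance = 1e-12)
  expect_equal(as.numeric(average_signatures(list(v, v))), as.numeric(v), tolerance = 1e-12)
  cancel <- average_signatures(list(v, -v))
  expect_true(attr(cancel, "degenerate"))
  expect_identical(attr(cancel, "n_source_profiles"), 2L)
})

test_that("6.4 h and 24.4 h collapse to 6 h and 24 h", {
  expect_identical(collapse_time(c(6.4, 24.4, 48, 6)), c(6, 24, 48, 6))
})

test_that("top/bottom selection keeps the k extremes and zeroes the rest", {
  v <- c(-3, -1, 0, 1, 3)
  expect_identical(as.numeric(select_top_bottom(v, 1)), c(-3, 0, 0, 0, 3))
  expect_identical(as.numeric(select_top_bottom(v, "all")), v)
  expect_error(select_top_bottom(v, 3), "k <= d/2")

  # retained entries keep sign and value; no new non-zeros; exactly 2k kept,
  # even with planted ties at the cut
  for (seed in 1:10) {
    v <- with_seed(seed, round(stats::rnorm(40), 1))  # rounding plants ties
    v[v == 0] <- 0.05  # keep entries non-zero so the 2k count is observable
    k <- with_seed(seed, sample(1:20, 1))
    out <- select_top_bottom(v, k)
    expect_identical(sum(out != 0), 2L * k)
    expect_true(all(out[out != 0] == v[out != 0]))
  }

  # lower index wins at an exact tie boundary
  tied <- c(5, 5, 5, -5, -5, -5)
  out <- select_top_bottom(tied, 1)
  expect_identical(which(out != 0), c(1L, 4L))
})

test_that("presets top50/top100 parse and mask accordingly", {
  v <- with_seed(1, stats::rnorm(978))
  expect_identical(sum(select_top_bottom(v, "top50") != 0), 100L)
  expect_identical(sum(select_top_bottom(v, "top100") != 0), 200L)
  expect_identical(sum(select_top_bottom(v, "top:7") != 0), 14L)
  expect_error(select_top_bottom(v, "bogus"), "preset")
})

test_that("build_signature_set does the full bookkeeping", {
  genes <- paste0("g", 1:20)
  cells <- c("A", "B")
  cpds <- c("c1", "c2")
  meta <- list()
  cols <- list()
  set.seed(7)
  base <- stats::setNames(runif(20, 50, 150), genes)
  for (cl in cells) {
    for (r in 1:2) {
      id <- sprintf("ctl_%s_r%d", cl, r)
      cols[[id]] <- base
      meta[[id]] <- data.frame(sample_id = id, role = "control", compound_id = "",
                               cell_line = cl, time_h = 6, dose = "", control_ref = "")
    }
  }
  for (cp in cpds) for (cl in cells) for (r in 1:2) {
    id <- sprintf("t_%s_%s_r%d", cp, cl, r)
    cols[[id]] <- base * exp(rnorm(20, 0, 0.3))
    meta[[id]] <- data.frame(sample_id = id, role = "treatment", compound_id = cp,
                             cell_line = cl, time_h = ifelse(r == 2, 6.4, 6),
                             dose = "10uM", control_ref = sprintf("ctl_%s_r%d", cl, r))
  }
  # one extra sample at 24 h that must be excluded by the time filter
  cols[["t_late"]] <- base
  meta[["t_late"]] <- data.frame(sample_id = "t_late", role = "treatment", compound_id = "c1",
                                 cell_line = "A", time_h = 24, dose = "10uM",
                                 control_ref = "ctl_A_r1")
  mat <- do.call(cbind, cols)
  rownames(mat) <- genes
  meta <- do.call(rbind, meta)

  set <- build_signature_set(mat, meta, "biological_control", time_filter = 6)
  expect_identical(ncol(set$values), 4L)  # 2 compounds x 2 cells
  expect_identical(unique(set$keys$n_source_profiles), 2L)  # 6 h + 6.4 h replicates
  expect_equal(unname(colMeans(set$values[, !set$keys$degenerate, drop = FALSE])),
               rep(0, sum(!set$keys$degenerate)), tolerance = 1e-9)

  # identical replicates give the replicate signature back
  mat2 <- mat
  mat2[, "t_c1_A_r2"] <- mat[, "t_c1_A_r1"]
  meta2 <- meta
  meta2$control_ref[meta2$sample_id == "t_c1_A_r2"] <- "ctl_A_r1"
  set2 <- build_signature_set(mat2, meta2, "biological_control")
  single <- signature_biological_control(mat2[, "t_c1_A_r1"], mat2[, "ctl_A_r1"])
  expect_equal(unname(set2$values[, "c1|A"]), unname(as.numeric(single)), tolerance = 1e-9)

  # unresolvable control is skipped with a warning, not an error
  meta3 <- meta
  meta3$control_ref[meta3$sample_id == "t_c2_B_r1"] <- "nonexistent"
  expect_warning(set3 <- build_signature_set(mat, meta3, "biological_control"),
                 "unresolvable")
  expect_identical(set3$keys$n_source_profiles[set3$keys$compound_id == "c2" &
                                               set3$keys$cell_line == "B"], 1L)

  # mean-centering groups by (cell line, control_ref)
  set4 <- build_signature_set(mat, meta, "mean_centering")
  expect_identical(ncol(set4$values), 4L)
})

test_that("signatures are standardized and correlation-invariant to it", {
  # Pearson correlation between two signatures is unchanged by the
  # centering/scaling step
  for (seed in 1:5) {
    lr1 <- with_seed(seed, stats::rnorm(100))
    lr2 <- with_seed(seed + 100, stats::rnorm(100) + 0.5 * lr1)
    expect_equal(stats::cor(lr1, lr2),
                 stats::cor(as.numeric(standardize(lr1)), as.numeric(standardize(lr2))),
                 tolerance = 1e-12)
  }
})
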