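# Synthetic-data generator: determinism, parameter validation, and the
# planted structure it promises.

test_that("fixed seed reproduces the dataset exactly and restores the RNG", {
  p <- simulation_params(n_genes = 100, n_cell_lines = 3, n_compounds = 8,
                         n_proteins = 5, n_pathways = 4, pathway_size = 25, seed = 9)
  set.seed(1234)
  before <- stats::runif(1)
  set.seed(1234)
  a <- simulate_dataset(p)
  after <- stats::runif(1)
  expect_identical(before, after)  # generator did not consume caller RNG
  b <- simulate_dataset(p)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(simulation_params(n_genes = 100, n_cell_lines = 3, n_compounds = 8,
                                          n_proteins = 5, n_pathways = 4, pathway_size = 25,
                                          seed = 10))
  expect_false(identical(a$expression, c$expression))
})

test_that("infeasible parameters are rejected up front", {
  expect_error(simulation_params(pathway_size = 2000), "pathway_size")
  expect_error(simulation_params(targets_per_compound = 50), "targets per compound")
  expect_error(simulation_params(fraction_profiled_cells = 0), "fraction_profiled_cells")
  expect_error(simulation_params(signature_noise_sd = -1), "sds")
})

test_that("the emitted tables are mutually consistent with the truth", {
  ds <- simulate_dataset(simulation_params(n_genes = 150, n_cell_lines = 4,
                                           n_compounds = 10, n_proteins = 6,
                                           n_pathways = 5, pathway_size = 30,
                                           fraction_profiled_cells = 0.5, seed = 2))
  # interactome mirrors the true target map
  for (cpd in names(ds$truth$targets)) {
    expect_setequal(targets_of(ds$interactome, cpd), ds$truth$targets[[cpd]])
  }
  # every compound profiled in ceiling(0.5 * 4) = 2 cells
  trt <- ds$metadata[ds$metadata$role == "treatment", ]
  cells_per_cpd <- tapply(trt$cell_line, trt$compound_id, function(x) length(unique(x)))
  expect_true(all(cells_per_cpd == 2))
  # compounds sharing a target share a disease
  t1 <- names(ds$truth$targets)[1]
  partner <- Find(function(c2) length(intersect(ds$truth$targets[[t1]],
                                                ds$truth$targets[[c2]])) > 0,
                  setdiff(names(ds$truth$targets), t1))
  if (!is.null(partner)) {
    d1 <- ds$indications$pairs$disease_id[ds$indications$pairs$compound_id == t1]
    d2 <- ds$indications$pairs$disease_id[ds$indications$pairs$compound_id == partner]
    expect_gt(length(intersect(d1, d2)), 0)
  }
  # pathway collection matches the truth membership
  for (pw in names(ds$pathways)) {
    expect_setequal(ds$pathways[[pw]]$members, ds$truth$pathway_members[[pw]])
  }
})

test_that("noise-free identical-target compounds have same-cell similarity 1", {
  p <- simulation_params(n_genes = 120, n_cell_lines = 2, n_compounds = 6,
                         n_proteins = 2, targets_per_compound = 2,
                         n_pathways = 1, pathway_size = 20,
                         signature_noise_sd = 0, pathway_effect_size = 0,
                         fraction_profiled_cells = 1, seed = 4)
  ds <- simulate_dataset(p)
  # all compounds bind both proteins and perturb the same (single) pathway,
  # so their signals are identical within a cell line
  set <- build_signature_set(ds$expression, ds$metadata, "biological_control")
  sim <- compound_similarity_matrix(set, set, "same")
  off <- sim$score[upper.tri(sim$score)]
  expect_true(all(abs(off - 1) < 1e-9))
})

test_that("the null generator removes all planted signal", {
  p <- simulation_params(n_genes = 100, n_cell_lines = 2, n_compounds = 5,
                         n_proteins = 4, n_pathways = 3, pathway_size = 25, seed = 6)
  nul <- simulate_null_dataset(p)
  expect_identical(nul$params$target_effect_size, 0)
  expect_identical(nul$params$pathway_effect_size, 0)
  # cross-cell signature pairs share nothing under the null (same-cell pairs
  # retain a uniform baseline correlation from the shared matched control,
  # as in real plate designs; rank-based metrics are unaffected by it)
  set <- build_signature_set(nul$expression, nul$metadata, "biological_control")
  sim <- compound_similarity_matrix(set, set, "different")
  off <- sim$score[upper.tri(sim$score)]
  expect_lt(max(abs(off)), 0.35)
})

test_that("stronger target effects monotonically improve recovery AUC", {
  aucs <- vapply(c(0.5, 1.0, 2.0), function(eff) {
    ds <- simulate_dataset(simulation_params(n_genes = 300, n_cell_lines = 3,
                                             n_compounds = 20, n_proteins = 10,
                                             n_pathways = 5, pathway_size = 40,
                                             target_effect_size = eff, seed = 8))
    set <- build_signature_set(ds$expression, ds$metadata, "biological_control")
    unname(run_cv(ds$interactome, set, n_folds = 5, seed = 1,
                  strategy = "same")$pooled["auc"])
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("a dataset roundtrips through the on-disk fixture formats", {
  ds <- simulate_dataset(simulation_params(n_genes = 80, n_cell_lines = 2,
                                           n_compounds = 4, n_proteins = 3,
                                           n_pathways = 3, pathway_size = 20, seed = 3))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  expect_equal(read_expression_matrix(file.path(dir, "expression.tsv")),
               ds$expression, tolerance = 1e-6)
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(meta$sample_id, ds$metadata$sample_id)
  it <- read_pair_table(file.path(dir, "interactome.tsv"), "interactome")
  expect_identical(it$pairs, ds$interactome$pairs)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(unlist(truth$targets[["cpd001"]]), ds$truth$targets[["cpd001"]])
})
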