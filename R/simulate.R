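# Synthetic chemically-induced transcriptome generator.
#
# Generative model (multiplicative lognormal on linear-scale expression, so
# log-ratio signatures are additive Gaussian):
#   baseline       B[g,c]  = exp(mu + N(0, cell_effect_sd))        per gene, cell
#   target effect  E[g,t]  = +-target_effect_size on a random ~5% of genes
#   cell response  D[g,t,c]= N(0, cell_effect_sd * target_effect_size) on the
#                            same support: the cell-specific part of the
#                            response to target t (and analogously for the
#                            planted pathway's effect)
#   signal S_c[g,i] = sum over compound i's targets of (E + D[, ,c])
#                     + pathway effect (+ its per-cell part) on i's pathway
#   control   = B[,c] * exp(N(0, signature_noise_sd))              per replicate
#   treatment = B[,c] * exp(S_c[,i] + N(0, signature_noise_sd))
#
# Cell identity therefore shapes both the baseline (driving Fig.1-style
# clustering of control profiles) and the response to perturbation: two
# compounds sharing a target induce the same cell-specific response in the
# same cell line but share only the cell-independent component across cell
# lines, which is what makes same-cell matching outperform different-cell
# matching as cell_effect_sd grows. Compounds sharing targets have
# correlated signatures; each compound additionally perturbs one planted
# pathway. Pathway sizes are drawn uniformly between 20 and `pathway_size`
# to emulate the size heterogeneity of real collections.

#' Simulation parameters
#'
#' Defaults mirror the landmark-gene data regime: 978 genes, compounds
#' profiled in a subset of cell lines, two targets per compound, with a
#' moderate signature noise floor.
#'
#' @param n_genes gene universe size (default 978, the landmark set size).
#' @param n_cell_lines number of cell lines (default 5).
#' @param n_compounds number of compounds (default 60).
#' @param n_proteins number of target proteins (default 30).
#' @param n_pathways number of pathways (default 20).
#' @param pathway_size maximum pathway size; sizes are drawn uniformly in
#'   `[20, pathway_size]` (default 120).
#' @param targets_per_compound true targets per compound (default 2).
#' @param cell_effect_sd sd of per-gene log baseline across cell lines, and
#'   (at half strength) of the per-cell log response gain (default 1.0).
#' @param signature_noise_sd sd of per-profile lognormal measurement noise
#'   (default 0.5).
#' @param target_effect_size magnitude of a target's per-gene log effect
#'   (default 2.0).
#' @param pathway_effect_size log up-regulation applied to the planted
#'   pathway's genes (default 1.0).
#' @param replicate_count treatment/control replicates per condition
#'   (default 2; the second replicate is measured at 6.4 h to exercise time
#'   collapsing).
#' @param fraction_profiled_cells fraction of cell lines each compound is
#'   profiled in (default 0.6).
#' @param seed integer seed.
#' @return validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 978, n_cell_lines = 5, n_compounds = 60,
                              n_proteins = 30, n_pathways = 20, pathway_size = 120,
                              targets_per_compound = 2, cell_effect_sd = 1.0,
                              signature_noise_sd = 0.5, target_effect_size = 2.0,
                              pathway_effect_size = 1.0, replicate_count = 2,
                              fraction_profiled_cells = 0.6, seed = 1) {
  p <- list(n_genes = n_genes, n_cell_lines = n_cell_lines, n_compounds = n_compounds,
            n_proteins = n_proteins, n_pathways = n_pathways, pathway_size = pathway_size,
            targets_per_compound = targets_per_compound, cell_effect_sd = cell_effect_sd,
            signature_noise_sd = signature_noise_sd, target_effect_size = target_effect_size,
            pathway_effect_size = pathway_effect_size, replicate_count = replicate_count,
            fraction_profiled_cells = fraction_profiled_cells, seed = seed)
  with(p, {
    if (n_genes < 2 || n_cell_lines < 1 || n_compounds < 1 || n_proteins < 1) {
      abort("simulation_params: sizes must be positive (n_genes >= 2)")
    }
    if (pathway_size > n_genes) abort("simulation_params: pathway_size exceeds n_genes")
    if (targets_per_compound > n_proteins) abort("simulation_params: more targets per compound than proteins")
    if (cell_effect_sd < 0 || signature_noise_sd < 0) abort("simulation_params: sds must be >= 0")
    if (target_effect_size < 0 || pathway_effect_size < 0) abort("simulation_params: effect sizes must be >= 0")
    if (fraction_profiled_cells <= 0 || fraction_profiled_cells > 1) {
      abort("simulation_params: fraction_profiled_cells must be in (0, 1]")
    }
    if (replicate_count < 1) abort("simulation_params: replicate_count must be >= 1")
  })
  structure(p, class = "simulation_params")
}

icd_chapters <- function() {
  as.character(utils::as.roman(1:22))
}

#' Simulate a complete synthetic dataset
#'
#' Generates linear-scale control and treatment expression profiles with
#' cell-line baseline effects, compounds with planted targets whose
#' shared-target pairs have correlated signatures, planted perturbed
#' pathways, and the accompanying interactome, indication and
#' chemical-feature tables, plus the ground truth. Deterministic given
#' `params$seed`; the caller's RNG state is untouched.
#'
#' @param params a `simulation_params` object.
#' @return list of class `synthetic_dataset` with elements `expression`
#'   (genes x samples matrix), `metadata`, `pathways`, `interactome`,
#'   `indications`, `features`, `truth`, `params`.
#' @export
simulate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, simulate_dataset_impl(params))
}

#' Simulate a matched null dataset
#'
#' Identical generative process with `target_effect_size` and
#' `pathway_effect_size` forced to zero: treatment profiles are pure noise
#' around the cell baselines. Used for type-I-error and AUC-null calibration.
#'
#' @inheritParams simulate_dataset
#' @export
simulate_null_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  params$target_effect_size <- 0
  params$pathway_effect_size <- 0
  simulate_dataset(params)
}

simulate_dataset_impl <- function(p) {
  genes <- sprintf("g%04d", seq_len(p$n_genes))
  cells <- sprintf("CL%02d", seq_len(p$n_cell_lines))
  cpds <- sprintf("cpd%03d", seq_len(p$n_compounds))
  prots <- sprintf("P%03d", seq_len(p$n_proteins))
  pws <- sprintf("pw%03d", seq_len(p$n_pathways))

  mu <- log(100)
  B <- exp(mu + matrix(stats::rnorm(p$n_genes * p$n_cell_lines, 0, p$cell_effect_sd),
                       p$n_genes, p$n_cell_lines, dimnames = list(genes, cells)))

  # target effect vectors: sparse, ~5% of genes at +-target_effect_size,
  # plus a cell-specific response component on the same support
  n_affected <- max(10L, round(0.05 * p$n_genes))
  E <- matrix(0, p$n_genes, p$n_proteins, dimnames = list(genes, prots))
  D <- array(0, c(p$n_genes, p$n_proteins, p$n_cell_lines),
             dimnames = list(genes, prots, cells))
  resp_sd <- p$cell_effect_sd * p$target_effect_size
  affected <- vector("list", p$n_proteins)
  names(affected) <- prots
  for (k in seq_len(p$n_proteins)) {
    idx <- sample.int(p$n_genes, n_affected)
    E[idx, k] <- sample(c(-1, 1), n_affected, replace = TRUE) * p$target_effect_size
    D[idx, k, ] <- stats::rnorm(n_affected * p$n_cell_lines, 0, resp_sd)
    affected[[k]] <- genes[idx]
  }

  # pathways with heterogeneous sizes
  lo <- min(20L, p$pathway_size)
  sizes <- sample(seq(lo, p$pathway_size), p$n_pathways, replace = TRUE)
  pw_members <- lapply(sizes, function(s) sort(sample(genes, s)))
  names(pw_members) <- pws
  pathways <- structure(
    lapply(pws, function(id) list(name = paste("synthetic pathway", id),
                                  members = pw_members[[id]])),
    names = pws, class = "pathway_collection")

  # compound wiring: targets, planted pathway, profiled cells
  targets <- lapply(seq_len(p$n_compounds), function(i) sort(sample(prots, p$targets_per_compound)))
  names(targets) <- cpds
  planted <- stats::setNames(sample(pws, p$n_compounds, replace = TRUE), cpds)
  n_prof <- max(1L, ceiling(p$fraction_profiled_cells * p$n_cell_lines))
  profiled <- lapply(seq_len(p$n_compounds), function(i) sort(sample(cells, n_prof)))
  names(profiled) <- cpds

  # cell-specific part of each pathway's perturbation effect
  pw_resp_sd <- p$cell_effect_sd * p$pathway_effect_size
  Dpw <- lapply(pws, function(pw) {
    m <- matrix(stats::rnorm(length(pw_members[[pw]]) * p$n_cell_lines, 0, pw_resp_sd),
                ncol = p$n_cell_lines, dimnames = list(pw_members[[pw]], cells))
    m
  })
  names(Dpw) <- pws

  # per-cell signal matrices: shared effect + that cell's response component
  S <- lapply(cells, function(cl) {
    s <- matrix(0, p$n_genes, p$n_compounds, dimnames = list(genes, cpds))
    for (i in seq_len(p$n_compounds)) {
      s[, i] <- rowSums(E[, targets[[i]], drop = FALSE]) +
        rowSums(D[, targets[[i]], cl, drop = FALSE])
      pw <- planted[i]
      s[pw_members[[pw]], i] <- s[pw_members[[pw]], i] + p$pathway_effect_size +
        Dpw[[pw]][, cl]
    }
    s
  })
  names(S) <- cells

  # samples: controls (replicate_count per cell line) then treatments
  noise <- function(n) exp(stats::rnorm(n, 0, p$signature_noise_sd))
  ctl_ids <- as.vector(t(outer(cells, seq_len(p$replicate_count),
                               function(cl, r) sprintf("ctl_%s_r%d", cl, r))))
  ctl_cell <- rep(cells, each = p$replicate_count)
  ctl_mat <- vapply(seq_along(ctl_ids), function(j) B[, ctl_cell[j]] * noise(p$n_genes),
                    numeric(p$n_genes))
  colnames(ctl_mat) <- ctl_ids

  trt_ids <- character(0)
  trt_meta <- list()
  trt_cols <- list()
  rep_time <- function(r) if (r %% 2L == 0L) 6.4 else 6  # sub-times collapse to 6 h
  for (i in seq_len(p$n_compounds)) {
    for (cl in profiled[[i]]) {
      for (r in seq_len(p$replicate_count)) {
        id <- sprintf("trt_%s_%s_r%d", cpds[i], cl, r)
        trt_ids <- c(trt_ids, id)
        trt_cols[[id]] <- B[, cl] * exp(S[[cl]][, i]) * noise(p$n_genes)
        trt_meta[[id]] <- data.frame(sample_id = id, role = "treatment",
                                     compound_id = cpds[i], cell_line = cl,
                                     time_h = rep_time(r), dose = "10uM",
                                     control_ref = sprintf("ctl_%s_r%d", cl, r),
                                     stringsAsFactors = FALSE)
      }
    }
  }
  expr <- cbind(ctl_mat, do.call(cbind, trt_cols))
  rownames(expr) <- genes
  meta <- rbind(
    data.frame(sample_id = ctl_ids, role = "control", compound_id = "",
               cell_line = ctl_cell, time_h = 6, dose = "",
               control_ref = "", stringsAsFactors = FALSE),
    do.call(rbind, trt_meta))
  rownames(meta) <- NULL

  interactome <- interactome_table(data.frame(
    compound_id = rep(cpds, each = p$targets_per_compound),
    protein_id = unlist(targets), stringsAsFactors = FALSE))

  # one disease per protein; compounds sharing a target share its disease
  diseases <- sprintf("dis%03d", seq_len(p$n_proteins))
  chapters <- stats::setNames(rep_len(icd_chapters(), p$n_proteins), diseases)
  ind_pairs <- data.frame(
    compound_id = rep(cpds, each = p$targets_per_compound),
    disease_id = diseases[match(unlist(targets), prots)], stringsAsFactors = FALSE)
  indications <- indication_table(ind_pairs, chapters)

  # chemical features: target-specific blocks plus random background, so
  # shared-target compounds have moderately higher generalized Jaccard
  target_feats <- lapply(prots, function(pr) {
    stats::setNames(sample(1:3, 25, replace = TRUE), sprintf("f_%s_%02d", pr, 1:25))
  })
  names(target_feats) <- prots
  bg_pool <- sprintf("fbg%03d", 1:200)
  features <- lapply(seq_len(p$n_compounds), function(i) {
    v <- unlist(target_feats[targets[[i]]], use.names = FALSE)
    names(v) <- unlist(lapply(target_feats[targets[[i]]], names), use.names = FALSE)
    bg <- stats::setNames(sample(1:3, 25, replace = TRUE), sample(bg_pool, 25))
    out <- c(v, bg)
    tapply(out, names(out), sum)[unique(names(out))]
  })
  names(features) <- cpds
  features <- structure(lapply(features, function(v) stats::setNames(as.numeric(v), names(v))),
                        class = "chemical_features")

  truth <- list(targets = targets, affected_genes = affected,
                pathway_members = pw_members, compound_pathway = as.list(planted),
                profiled_cells = profiled, cell_lines = cells)

  structure(list(expression = expr, metadata = meta, pathways = pathways,
                 interactome = interactome, indications = indications,
                 features = features, truth = truth, params = p),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes, %d samples (%d compounds x %d cell lines), %d proteins, %d pathways\n",
              nrow(x$expression), ncol(x$expression), x$params$n_compounds,
              x$params$n_cell_lines, x$params$n_proteins, x$params$n_pathways))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits all fixture files in the package's TSV/GMT dialects plus
#' `truth.json`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(ds$expression, file.path(dir, "expression.tsv"))
  write_sample_metadata(ds$metadata, file.path(dir, "metadata.tsv"))
  write_gmt(ds$pathways, file.path(dir, "pathways.gmt"))
  write_pair_table(ds$interactome, file.path(dir, "interactome.tsv"))
  write_pair_table(ds$indications, file.path(dir, "indications.tsv"))
  write_pair_table(ds$features, file.path(dir, "features.tsv"))
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
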