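# Independent oracles used to cross-check the package's statistics.
# These deliberately use brute force / naive formulations, not the
# implementations under test.

# Upper-tail hypergeometric by exhaustive enumeration: draw every r-subset of
# 1:l, take the pathway to be 1:k, and count draws with intersection >= z.
hyper_tail_enum <- function(z, r, k, l) {
  if (z <= 0) return(1)
  subsets <- utils::combn(l, r)
  overlaps <- colSums(subsets <= k)
  mean(overlaps >= z)
}

# Benjamini-Hochberg step-up, written from the definition:
# p_adj(i) = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  pmin(adj, 1)[order(o)]
}

# ROC-AUC by counting concordant positive-negative pairs (ties = 1/2).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small synthetic fixture shared by several test files (cheap: ~200 genes).
small_fixture <- function(seed = 42, ...) {
  params <- simulation_params(n_genes = 200, n_cell_lines = 3, n_compounds = 15,
                              n_proteins = 8, n_pathways = 6, pathway_size = 40,
                              seed = seed, ...)
  ds <- simulate_dataset(params)
  set <- build_signature_set(ds$expression, ds$metadata, "biological_control")
  list(ds = ds, set = set)
}

# Locate the installed CLI script and run a subcommand in a subprocess with
# the current library path propagated.
run_cli <- function(args, dir) {
  cli <- system.file("cli", "sigmoa.R", package = "sigmoa")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(cli), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) stop("CLI failed: ", paste(out, collapse = "\n"))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
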