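# Hypergeometric pathway enrichment of regulated genes.
#
# For each compound signature the top and bottom fractions of genes are taken
# as upregulated and downregulated sets; each pathway is tested for
# over-representation of each set against the signature's gene universe
# (l genes, the landmark universe) with an upper-tail hypergeometric test,
# and p-values are FDR-adjusted across the pathway family per direction.

#' Extract up- and down-regulated gene sets from a signature
#'
#' The genes ranked in the top and bottom `fraction` of the signature
#' (default the top and bottom 5%). Set sizes are `floor(fraction * d)`;
#' ties at a cut are broken stably by gene index (up-set first, down-set from
#' the remaining genes), so the two sets never overlap for fraction < 0.5.
#' A degenerate (all-zero) signature yields empty sets with a warning.
#'
#' @param sig named signature vector.
#' @param fraction fraction of genes per side, in (0, 0.5).
#' @return list with `up`, `down` (character vectors of gene ids),
#'   `fraction`, `n_per_side`.
#' @export
select_regulated_genes <- function(sig, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 0.5) abort("fraction must be in (0, 0.5)")
  if (is.null(names(sig))) abort("select_regulated_genes: signature must carry gene names")
  d <- length(sig)
  n <- floor(fraction * d)
  if (is_degenerate(sig) || all(sig == 0)) {
    warning("degenerate signature: returning empty regulated gene sets")
    return(list(up = character(), down = character(), fraction = fraction, n_per_side = n))
  }
  idx <- seq_len(d)
  up_idx <- idx[order(-sig, idx)][seq_len(n)]
  rest <- setdiff(idx, up_idx)
  down_idx <- rest[order(sig[rest], rest)][seq_len(n)]
  list(up = names(sig)[up_idx], down = names(sig)[down_idx],
       fraction = fraction, n_per_side = n)
}

#' Upper-tail hypergeometric p-value for a pathway overlap
#'
#' Probability of observing an intersection of size at least `z` between a
#' regulated gene set of size `r` and a pathway of size `k` drawn from a
#' universe of `l` genes:
#' \deqn{P(X \ge z) = \sum_{i=z}^{\min(r,k)} \frac{\binom{k}{i}\binom{l-k}{r-i}}{\binom{l}{r}}.}
#' The sum is accumulated in log space for numerical stability. The inclusive
#' upper tail is the standard enrichment convention; `z = 0` always gives 1.
#'
#' @param z intersection size.
#' @param r regulated-set size.
#' @param k pathway size within the universe.
#' @param l universe size.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' hypergeom_pvalue(3, 4, 5, 10)  # 55/210
hypergeom_pvalue <- function(z, r, k, l) {
  if (any(c(z, r, k, l) < 0) || r > l || k > l) abort("hypergeom_pvalue: invalid counts")
  if (z > min(r, k)) abort("hypergeom_pvalue: z exceeds min(r, k)")
  if (z <= 0) return(1)
  i <- z:min(r, k)
  log_terms <- lchoose(k, i) + lchoose(l - k, r - i) - lchoose(l, r)
  min(exp(logsumexp(log_terms)), 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values in the input order; each adjusted value is at
#' least its raw value and the adjustment is monotone in rank.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
adjust_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p) | p <= 0 | p > 1)) abort("adjust_fdr: p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric enrichment of regulated gene sets over a pathway collection
#'
#' Tests each pathway for over-representation of the up- and down-regulated
#' sets. Pathway sizes `k` count only members inside the signature universe;
#' pathways empty after intersection are skipped with a message. FDR
#' adjustment is applied across the pathway family separately per direction.
#' The significance flag uses raw p-values by default (`threshold_on =
#' "raw"`); adjusted p-values are always reported and can drive the flag
#' instead.
#'
#' @param reg regulated gene sets from [select_regulated_genes()].
#' @param pathways a pathway collection from [read_gmt()].
#' @param universe character vector: the l signature genes.
#' @param alpha significance level (default 0.05).
#' @param threshold_on `"raw"` or `"fdr"`.
#' @return data.frame with one row per (direction, pathway): `direction`,
#'   `pathway`, `z`, `r`, `k`, `l`, `p_raw`, `p_adj`, `significant`.
#' @export
enrich_pathways <- function(reg, pathways, universe, alpha = 0.05,
                            threshold_on = c("raw", "fdr")) {
  threshold_on <- match.arg(threshold_on)
  l <- length(universe)
  members <- lapply(pathways, function(p) intersect(p$members, universe))
  k <- lengths(members)
  if (any(k == 0L)) {
    message(sprintf("skipping %d pathway(s) with no members in the universe", sum(k == 0L)))
  }
  ids <- names(pathways)[k > 0L]
  members <- members[k > 0L]
  k <- k[k > 0L]
  res <- lapply(c("up", "down"), function(dir) {
    genes <- reg[[dir]]
    r <- length(genes)
    z <- vapply(members, function(m) length(intersect(genes, m)), integer(1L))
    p_raw <- vapply(seq_along(z), function(i) hypergeom_pvalue(z[i], r, k[i], l), numeric(1L))
    data.frame(direction = dir, pathway = ids, z = z, r = r, k = as.integer(k), l = l,
               p_raw = p_raw, p_adj = adjust_fdr(p_raw),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$significant <- (if (threshold_on == "raw") out$p_raw else out$p_adj) < alpha
  out
}

#' Enrichment across a whole signature set
#'
#' Runs [select_regulated_genes()] and [enrich_pathways()] for every
#' non-degenerate signature in the set.
#'
#' @param set a `signature_set`.
#' @param pathways a pathway collection.
#' @param fraction regulated fraction per side (default 0.05).
#' @inheritParams enrich_pathways
#' @return long data.frame with `compound_id` and `cell_line` prepended.
#' @export
enrich_signature_set <- function(set, pathways, fraction = 0.05, alpha = 0.05,
                                 threshold_on = c("raw", "fdr")) {
  threshold_on <- match.arg(threshold_on)
  universe <- set$gene_ids
  rows <- lapply(which(!set$keys$degenerate), function(j) {
    sig <- set$values[, j]
    reg <- select_regulated_genes(sig, fraction)
    res <- enrich_pathways(reg, pathways, universe, alpha, threshold_on)
    cbind(data.frame(compound_id = set$keys$compound_id[j],
                     cell_line = set$keys$cell_line[j],
                     stringsAsFactors = FALSE),
          res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pathway detection frequency tables
#'
#' Summarizes enrichment results: how many compounds significantly activate
#' or inactivate each pathway, and how many pathways are detected per
#' compound. The two tables double-count the same significant records, so
#' their totals agree.
#'
#' @param results long enrichment data.frame from [enrich_signature_set()].
#' @return list with `pathway_counts` (pathway x direction counts) and
#'   `compound_counts` (per compound x direction counts).
#' @export
pathway_frequency_table <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  all_pathways <- sort(unique(results$pathway))
  all_compounds <- sort(unique(results$compound_id))
  count_by <- function(keys, universe_keys) {
    up <- table(factor(keys$pathway_or_cpd[keys$direction == "up"], levels = universe_keys))
    down <- table(factor(keys$pathway_or_cpd[keys$direction == "down"], levels = universe_keys))
    data.frame(id = universe_keys, up = as.integer(up), down = as.integer(down),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  pc <- count_by(data.frame(pathway_or_cpd = sig$pathway, direction = sig$direction),
                 all_pathways)
  names(pc)[1L] <- "pathway"
  cc <- count_by(data.frame(pathway_or_cpd = sig$compound_id, direction = sig$direction),
                 all_compounds)
  names(cc)[1L] <- "compound_id"
  list(pathway_counts = pc, compound_counts = cc)
}
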