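---
title: "Methods: signatures, enrichment, similarity search and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signatures, enrichment, similarity search and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmoa)
```

`sigmoa` infers the mode of action of a bioactive compound from its
chemically-induced transcriptome response: which pathways it activates or
inactivates, which proteins it is likely to bind, and which diseases it
might therefore treat. This vignette documents the statistical machinery,
the choices that were genuinely open, and what the synthetic benchmark does
and does not establish.

## Signature model

A *signature* for one (compound, cell line) is the vector of per-gene log
ratios of treated to control expression, standardized to mean 0 and
standard deviation 1. Standardization uses the population denominator
(`d`, not `d − 1`); the choice is immaterial downstream because Pearson
correlation — the only consumer of signatures — is invariant to centering
and scaling, but fixing it makes results bit-reproducible. The log base
defaults to 2 and is likewise immaterial after standardization.

Two normalizations are available:

* **Biological control**: ratio of each treatment profile against its
  matched control profile (linked via `control_ref` in the metadata).
* **Mean centering**: ratio against the *averaged control profile*, the
  per-gene mean of all treatment profiles sharing one control condition
  (grouping key: cell line × `control_ref`). This emulates the
  batch-effect-reducing population normalization used with robust z-score
  style data; it requires at least two profiles per group.

Numerical guards: linear expression values are floored at
`epsilon = 0.01` before the ratio so zero counts never produce infinite
ratios (expression units are arbitrary linear scale; 0.01 is far below any
real signal). A constant log-ratio vector has no scale; it becomes the
all-zero vector flagged *degenerate* rather than an error, and degenerate
signatures are excluded from all similarity maxima and from regulated-gene
selection.

**Averaging order.** Replicates, doses and collapsed sub-times (6.4 h is
regarded as 6 h, 24.4 h as 24 h) are integrated by arithmetic averaging
within each (compound, cell line). Whether averaging happens before or
after standardization is not dictated by the signature definition; this
package standardizes each profile first, averages, then re-standardizes.
Per-profile standardization stops a single high-variance replicate from
dominating the mean, and the final re-standardization restores the unit
scale; all doses and replicates carry equal weight. By default only the
6-hour time point is used.

**Top/bottom masking.** Small expression ratios are mostly noise, so the
signature can be masked to its `k` largest and `k` smallest entries
(presets `top50`, `top100`, `all`), the rest set to zero. Ties at a cut are
resolved stably by gene index — the top block is filled first, the bottom
block from the remaining genes — so the output always has exactly `2k`
non-zeros, even when a tie block spans both cuts.

## Pathway enrichment

For each non-degenerate signature the top and bottom `fraction` of genes
(default 0.05 per side, i.e. `floor(0.05 · l)` genes; 48 when `l = 978`)
form the up- and down-regulated sets. Each pathway is tested for
over-representation with the hypergeometric upper tail
`P(X ≥ z)`, accumulated in log space (`lchoose` + log-sum-exp) so that
universes of hundreds of genes lose no precision. The *inclusive* upper
tail is used: the point-probability formulation describes the chance of an
intersection of exactly size `z`, but a significance statement needs the
tail, and `P(X ≥ z)` is the standard enrichment convention (`z = 0` gives
p = 1 identically). Pathway size `k` counts only members inside the
signature universe; pathways empty after intersection are skipped.

FDR correction is Benjamini–Hochberg, applied per compound and per
direction across the loaded pathway family. The significance flag defaults
to the raw p-value at `alpha = 0.05` — mirroring how detections are usually
reported in this setting — but the adjusted p-value is always emitted and
can drive the flag instead (`threshold_on = "fdr"`).

Note the test is discrete: with `r = 48`, `l = 978` and realistic pathway
sizes the attainable type-I rate at a nominal 0.05 is approximately 0.03,
because the rejection boundary can only sit on attainable values of `z`.
The null-calibration check in the test suite measures exactly this
conservative behavior.

## Similarity search and prediction

Transcriptional similarity between two compounds is the Pearson
correlation of their signatures, maximized over cell-line pairings:

* *same cell line-matching* — max over cell lines in which **both**
  compounds were profiled;
* *different cell line-matching* — max over ordered pairs of distinct cell
  lines;
* *all cell line-matching* — max of the two (defined if either is).

When no admissible pairing exists the score is *undefined*: a typed `NA`
sentinel, not a number. Downstream code treats it as "no evidence"; where a
complete numeric matrix is required (merged-protocol evaluation), undefined
scores fill as 0. Ties in any maximum are broken lexicographically (cell
line, then compound id) for provenance reporting only — the score itself is
unaffected.

The prediction score of a query compound for protein *k* is the maximum
similarity to any interactome compound binding *k*; the best-matching
compound and cell pair are recorded. Every reported score is a realized
pairwise correlation, never an interpolation. Large-scale runs threshold at
the upper 5th percentile of the pooled defined-score distribution
(nearest-rank: the cutoff is the `ceiling(0.05 n)`-th largest score, ties
at the cutoff included — deterministic and inclusive), with known pairs
removed from the "new prediction" set.

Indication transfer: a disease is predicted when an interactome compound
with that known indication shares at least one protein with the query's
predicted-target set; the transferred score is the target-prediction score
realized through the most similar qualifying compound. "Shares the same
targets" is interpreted as: the reference compound's *known* targets
intersect the query's *predicted* set at the current threshold, and the
per-disease maximum over qualifying compounds is taken (a global-best
variant would pick one donor compound for all diseases; the per-disease max
uses strictly more evidence and keeps scores a subset of target-prediction
scores). Repositioning summaries attribute each drug to the chapter of its
lexicographically first known indication so the chapter-move matrix totals
exactly one count per (drug, newly predicted chapter).

Chemical similarity of substructure count vectors uses the generalized
Jaccard coefficient `Σ_f min(u_f, v_f) / Σ_f max(u_f, v_f)`, which reduces
to the Tanimoto coefficient on binary fingerprints.

## Cross-validated evaluation

Fivefold cross-validation splits *compounds* (never proteins) into folds of
near-equal size; each fold's compound–protein pairs are scored against the
training interactome only, so a test compound can never match itself.
Negatives are all pairs absent from the gold standard (closed-world).
ROC-AUC uses the rank-sum formulation with ties counted ½ and is exact;
PR-AUC integrates precision against recall step-wise (no linear
interpolation) at distinct score thresholds. Metrics are pooled over the
folds' test pairs (per-fold values are also reported); pooling is the
default because fold-level positive counts can be tiny.

Two protocols: *common* evaluates only gold compounds with usable
signatures; *merged* evaluates all gold compounds and zero-fills the scores
of compounds lacking expression data, which degrades the measured AUC as
the zero-filled fraction grows.

## The synthetic benchmark

The generator produces linear-scale expression with a multiplicative
lognormal model, so log-ratio signatures are additive Gaussian — the
simplest model consistent with log-ratio + Pearson machinery:

* per-gene, per-cell baselines `exp(log 100 + N(0, cell_effect_sd))`;
* each target protein owns a sparse effect vector: ±`target_effect_size`
  on a random ~5% of genes, **plus a cell-specific response component**
  `N(0, cell_effect_sd · target_effect_size)` on the same support (and
  analogously for the planted pathway effect). Cell identity thus shapes
  both the baseline transcriptome and the response to perturbation: two
  compounds sharing a target look alike within a cell line but share only
  the cell-independent response across cell lines. Without this coupling a
  log-ratio cancels the baseline exactly and no amount of baseline
  variation could distort cross-cell comparisons — the very phenomenon the
  same-cell strategy exists for;
* each compound sums its targets' effects, up-regulates one planted
  pathway by `pathway_effect_size`, and is profiled in
  `ceiling(fraction_profiled_cells · n_cell_lines)` random cell lines with
  `replicate_count` replicates (the second replicate at 6.4 h, exercising
  time collapsing);
* treatments in one cell/replicate share their matched control profile, as
  in real plate designs. This induces a uniform positive baseline
  correlation among same-cell signatures (≈0.5 at the default noise level)
  even under the null; rank-based metrics are unaffected by a uniform
  shift, and the null CV-AUC stays at 0.5;
* pathway sizes are drawn uniformly in `[20, pathway_size]` (default max
  120) to emulate the size heterogeneity of real collections; indications
  assign one disease per protein so compounds sharing targets share a
  disease; chemical feature vectors combine target-specific substructure
  blocks with random background so shared-target pairs are moderately more
  Tanimoto-similar.

Defaults (978 genes, 5 cell lines, 60 compounds, 30 proteins, 2 targets
per compound, `target_effect_size = 2`, `signature_noise_sd = 0.5`,
`cell_effect_sd = 1`, 60% of cells profiled) define the benchmark study
conditions used throughout the tests and the acceptance script; the
matched null generator zeroes both effect sizes. The strategy-ordering and
clustering checks raise `cell_effect_sd` to 2, and enrichment recovery
raises `pathway_effect_size` to 2, as their study conditions.

What passing these tests shows: the pipeline recovers planted structure of
realistic dimensionality and noise, its statistics are calibrated on null
data, and every component agrees with independent oracles (exhaustive
hypergeometric enumeration, step-up BH, concordant-pair AUC). What it does
not show: performance on real data, where gene–gene covariance, dose
nonlinearity, batch structure beyond shared controls, and biased
interactome coverage all matter and none is modeled here.

## Known limitations

* Nearest-neighbor transfer cannot distinguish target activation from
  inhibition, and inherits any bias in the interactome's coverage.
* The discrete hypergeometric test is conservative at small regulated-set
  sizes (see above); FDR families are per compound × direction only.
* Undefined similarities (no shared cell line under same-cell matching)
  silently become "no evidence"; with very sparse cell coverage the
  same-cell strategy may score almost nothing.
* The generator's independence assumptions (genes independent given cell
  and compound) make its benchmarks necessary, not sufficient, evidence
  for real-data performance.
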