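Package: sigmoa
Title: Mode-of-Action Elucidation from Chemically-Induced Gene Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for elucidating modes of action of bioactive compounds from
    chemically-induced transcriptome data. Builds standardized log-ratio gene
    expression signatures from treatment/control profiles (biological-control or
    mean-centering normalization), identifies activated and inactivated pathways
    by hypergeometric enrichment of the top and bottom regulated genes with FDR
    correction, predicts target proteins by cell-line-matched nearest-neighbor
    transcriptional similarity search against a compound-protein interactome,
    transfers therapeutic indications from similar compounds, and evaluates
    predictions by fivefold compound-split cross-validation (ROC-AUC, PR-AUC).
    Includes a synthetic-data generator emulating cell-specific control baselines,
    target-driven correlated signatures and planted perturbed pathways, and a
    command-line interface over TSV/GMT formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
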