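# Readers and writers for the pipeline's tabular formats.
#
# Canonical dialect: tab-separated UTF-8, '#' comment lines ignored, header
# row where stated. Identifiers are opaque strings; no ontology resolution.
# Output ordering is deterministic (lexicographic by key) so files diff.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a gene expression matrix
#'
#' Parses a TSV with a header row of sample identifiers and gene identifiers
#' in the first column into a genes-by-samples numeric matrix of linear-scale
#' expression levels.
#'
#' @param path path to a TSV file; `#` comment lines are ignored.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) < 2L) abort("expression matrix %s: need a header and at least one gene row", path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) abort("expression matrix %s: header must name at least one sample", path)
  sample_ids <- header[-1L]
  ncol_exp <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != ncol_exp)) {
    bad <- which(widths != ncol_exp)[1L]
    abort("expression matrix %s: ragged row at line %d (%d fields, expected %d)",
          path, tl$lineno[-1L][bad], widths[bad], ncol_exp)
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(sample_ids)))
  )
  vals <- matrix(vals, nrow = length(sample_ids))  # samples x genes at this point
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    abort("expression matrix %s: non-numeric value for gene '%s', sample '%s'",
          path, gene_ids[idx[2L]], sample_ids[idx[1L]])
  }
  mat <- t(vals)
  rownames(mat) <- gene_ids
  colnames(mat) <- sample_ids
  validate_expression_matrix(mat, what = path)
  mat
}

#' @rdname read_expression_matrix
#' @param mat genes-by-samples numeric matrix.
#' @export
write_expression_matrix <- function(mat, path) {
  validate_expression_matrix(mat)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(v) paste(sprintf("%.10g", v), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

validate_expression_matrix <- function(mat, what = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat)) abort("%s: not a numeric matrix", what)
  if (nrow(mat) < 2L) abort("%s: need at least 2 genes", what)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) abort("%s: gene and sample names required", what)
  dup <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup)) abort("%s: duplicate gene id '%s'", what, dup[1L])
  dup <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup)) abort("%s: duplicate sample id '%s'", what, dup[1L])
  if (!all(is.finite(mat))) abort("%s: non-finite values present", what)
  if (any(mat < 0)) abort("%s: negative expression values present", what)
  invisible(mat)
}

#' Read or write a sample metadata table
#'
#' The metadata table links treatment samples to their matched control
#' samples. Columns: `sample_id`, `role` (`treatment` or `control`),
#' `compound_id` (empty for controls), `cell_line`, `time_h`, `dose`,
#' `control_ref` (the matched control's `sample_id`; treatments only).
#'
#' @param path path to a TSV file with a header row.
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", quote = "", check.names = TRUE)
  need <- c("sample_id", "role", "compound_id", "cell_line", "time_h", "dose", "control_ref")
  missing <- setdiff(need, names(df))
  if (length(missing)) abort("sample metadata %s: missing column(s) %s", path, paste(missing, collapse = ", "))
  df <- df[need]
  df$time_h <- as.numeric(df$time_h)
  validate_sample_metadata(df, what = path)
  df
}

#' @rdname read_sample_metadata
#' @param meta sample metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  validate_sample_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

validate_sample_metadata <- function(meta, what = "sample metadata", check_refs = TRUE) {
  if (anyDuplicated(meta$sample_id)) {
    abort("%s: duplicate sample id '%s'", what, meta$sample_id[duplicated(meta$sample_id)][1L])
  }
  if (!all(meta$role %in% c("treatment", "control"))) abort("%s: role must be treatment|control", what)
  if (any(!is.finite(meta$time_h) | meta$time_h <= 0)) abort("%s: time_h must be > 0", what)
  trt <- meta[meta$role == "treatment", ]
  has_ref <- nzchar(trt$control_ref)
  if (check_refs && any(has_ref)) {
    ctrl <- meta[meta$role == "control", ]
    ref_cell <- ctrl$cell_line[match(trt$control_ref[has_ref], ctrl$sample_id)]
    bad <- is.na(ref_cell) | ref_cell != trt$cell_line[has_ref]
    if (any(bad)) {
      abort("%s: control_ref '%s' of treatment '%s' does not resolve to a control in the same cell line",
            what, trt$control_ref[has_ref][bad][1L], trt$sample_id[has_ref][bad][1L])
    }
  }
  invisible(meta)
}

#' Read a GMT pathway collection
#'
#' Standard Broad-style GMT: one pathway per line, tab-separated fields
#' `pathway_id`, `description`, then member gene identifiers. Duplicate
#' members within a line are deduplicated. Universe membership is checked at
#' enrichment time, not load time.
#'
#' @param path path to a GMT file.
#' @return named list of pathways, each `list(name=, members=)`.
#' @export
read_gmt <- function(path) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines)) {
    warning(sprintf("GMT file %s is empty; returning an empty collection", path))
    return(structure(list(), class = "pathway_collection"))
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    abort("GMT file %s: line %d has fewer than 3 fields", path, tl$lineno[which(short)[1L]])
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) abort("GMT file %s: duplicate pathway id '%s'", path, ids[duplicated(ids)][1L])
  out <- lapply(fields, function(f) list(name = f[[2L]], members = unique(f[-(1:2)])))
  names(out) <- ids
  structure(out, class = "pathway_collection")
}

#' @rdname read_gmt
#' @param pathways a pathway collection.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(id) {
    p <- pathways[[id]]
    paste(c(id, p$name, p$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a pair or feature-count table
#'
#' One reader for the three sparse tables the pipeline consumes:
#' \describe{
#'   \item{interactome}{2 columns `compound_id`, `protein_id`; binary incidence.}
#'   \item{indication}{2 or 3 columns `compound_id`, `disease_id`, optional ICD
#'     chapter label for the disease (defaults to `"unknown"`).}
#'   \item{features}{3 columns `compound_id`, `feature_id`, non-negative integer
#'     count (chemical substructure frequencies).}
#' }
#' Duplicate pairs are deduplicated; for features, duplicate triplets must not
#' conflict.
#'
#' @param path path to a header-less TSV.
#' @param kind one of `"interactome"`, `"indication"`, `"features"`.
#' @return a classed incidence structure (see Details).
#' @export
read_pair_table <- function(path, kind = c("interactome", "indication", "features")) {
  kind <- match.arg(kind)
  tl <- read_tsv_lines(path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- switch(kind, interactome = 2L, indication = c(2L, 3L), features = 3L)
  bad <- !(nf %in% want)
  if (any(bad)) {
    abort("%s table %s: malformed line %d (%d fields)", kind, path,
          tl$lineno[which(bad)[1L]], nf[which(bad)[1L]])
  }
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  if (kind == "features") {
    cnt <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt))) {
      bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))[1L]
      abort("features table %s: invalid count at line %d", path, tl$lineno[bad])
    }
    key <- paste(a, b, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      first <- match(key[dup], key)
      if (any(cnt[dup] != cnt[first])) abort("features table %s: conflicting counts for a (compound, feature) pair", path)
      a <- a[!dup]; b <- b[!dup]; cnt <- cnt[!dup]
    }
    vecs <- lapply(split(seq_along(a), a), function(i) {
      v <- cnt[i]
      names(v) <- b[i]
      v[v > 0]
    })
    return(structure(vecs, class = "chemical_features"))
  }
  if (kind == "indication") {
    chap <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "unknown", character(1L))
    dup <- duplicated(paste(a, b, sep = "\r"))
    pairs <- data.frame(compound_id = a[!dup], disease_id = b[!dup], stringsAsFactors = FALSE)
    chapters <- tapply(chap, b, function(x) x[1L])
    chapters <- stats::setNames(as.character(chapters), names(chapters))
    return(indication_table(pairs, chapters))
  }
  dup <- duplicated(paste(a, b, sep = "\r"))
  interactome_table(data.frame(compound_id = a[!dup], protein_id = b[!dup], stringsAsFactors = FALSE))
}

#' Construct an interactome (compound x protein incidence) table
#'
#' @param pairs data.frame with columns `compound_id`, `protein_id`.
#' @return object of class `interactome_table` with `$pairs`, `$compounds`,
#'   `$proteins`.
#' @export
interactome_table <- function(pairs) {
  stopifnot(all(c("compound_id", "protein_id") %in% names(pairs)))
  pairs <- unique(pairs[c("compound_id", "protein_id")])
  pairs <- pairs[order(pairs$compound_id, pairs$protein_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 compounds = sort(unique(pairs$compound_id)),
                 proteins = sort(unique(pairs$protein_id))),
            class = "interactome_table")
}

#' @rdname interactome_table
#' @param x an `interactome_table`.
#' @param compound a compound id.
#' @export
targets_of <- function(x, compound) {
  x$pairs$protein_id[x$pairs$compound_id == compound]
}

#' @rdname interactome_table
#' @param protein a protein id.
#' @export
binders_of <- function(x, protein) {
  x$pairs$compound_id[x$pairs$protein_id == protein]
}

#' Construct an indication (compound x disease) table
#'
#' @param pairs data.frame with columns `compound_id`, `disease_id`.
#' @param chapters named character vector mapping disease ids to ICD chapter
#'   labels; unmapped diseases are bucketed as `"unknown"`.
#' @return object of class `indication_table`.
#' @export
indication_table <- function(pairs, chapters = character()) {
  stopifnot(all(c("compound_id", "disease_id") %in% names(pairs)))
  pairs <- unique(pairs[c("compound_id", "disease_id")])
  pairs <- pairs[order(pairs$compound_id, pairs$disease_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, chapters = chapters), class = "indication_table")
}

#' @rdname read_pair_table
#' @param x table object produced by [read_pair_table()] or constructed in code.
#' @export
write_pair_table <- function(x, path) {
  if (inherits(x, "chemical_features")) {
    rows <- do.call(rbind, lapply(sort(names(x)), function(cpd) {
      v <- x[[cpd]]
      o <- order(names(v))
      data.frame(a = cpd, b = names(v)[o], c = sprintf("%d", as.integer(v[o])))
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, fileEncoding = "UTF-8")
  } else if (inherits(x, "indication_table")) {
    p <- x$pairs
    chap <- x$chapters[p$disease_id]
    chap[is.na(chap)] <- "unknown"
    utils::write.table(data.frame(p$compound_id, p$disease_id, chap), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  } else if (inherits(x, "interactome_table")) {
    utils::write.table(x$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, fileEncoding = "UTF-8")
  } else {
    abort("write_pair_table: unsupported object of class %s", class(x)[1L])
  }
  invisible(path)
}

#' Write prediction scores
#'
#' Writes a TSV with columns `query_compound`, `target`, `score`,
#' `best_match_compound`, `best_match_cell_line`, in lexicographic row order.
#' Undefined scores (no comparable reference signature) are written as `NA`.
#'
#' @param scores data.frame of class `prediction_scores`.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  need <- c("query_compound", "target", "score", "best_match_compound", "best_match_cell_line")
  missing <- setdiff(need, names(scores))
  if (length(missing)) abort("write_scores: missing column(s) %s", paste(missing, collapse = ", "))
  scores <- scores[order(scores$query_compound, scores$target), need, drop = FALSE]
  out <- scores
  out$score <- ifelse(is.na(scores$score), "NA", sprintf("%.6f", scores$score))
  out$best_match_compound[is.na(out$best_match_compound)] <- "NA"
  out$best_match_cell_line[is.na(out$best_match_cell_line)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", quote = "")
  df$score <- as.numeric(df$score)
  class(df) <- c("prediction_scores", "data.frame")
  df
}

#' Write or read a signature set
#'
#' The signature matrix is written genes-by-signatures with columns keyed
#' `compound|cell_line`; the companion key table carries the per-signature
#' metadata (compound, cell line, time, number of source profiles, degeneracy).
#'
#' @param set a `signature_set`.
#' @param values_path path for the signature matrix TSV.
#' @param key_path path for the key table TSV.
#' @export
write_signature_set <- function(set, values_path, key_path) {
  stopifnot(inherits(set, "signature_set"))
  con <- file(values_path, open = "wt", encoding = "UTF-8")
  writeLines(paste(c("gene", colnames(set$values)), collapse = "\t"), con)
  body <- apply(set$values, 1L, function(v) paste(sprintf("%.10g", v), collapse = "\t"))
  writeLines(paste(set$gene_ids, body, sep = "\t"), con)
  close(con)
  utils::write.table(set$keys, key_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(values_path)
}

#' @rdname write_signature_set
#' @export
read_signature_set <- function(values_path, key_path) {
  tl <- read_tsv_lines(values_path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- fields[[1L]][-1L]
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- vapply(body, function(f) as.numeric(f[-1L]), numeric(length(header)))
  vals <- t(matrix(vals, nrow = length(header)))
  rownames(vals) <- gene_ids
  colnames(vals) <- header
  keys <- utils::read.delim(key_path, header = TRUE, sep = "\t", colClasses = "character", quote = "")
  keys$time_h <- as.numeric(keys$time_h)
  keys$n_source_profiles <- as.integer(keys$n_source_profiles)
  keys$degenerate <- as.logical(keys$degenerate)
  signature_set(vals, keys)
}
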