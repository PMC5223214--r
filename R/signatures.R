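# Construction of chemically-induced gene expression signatures.
#
# A signature is the per-gene log ratio of treated to control expression for
# one (compound, cell line), centered to mean zero and scaled to unit
# standard deviation. Two normalizations are supported: "biological control"
# (ratio against the matched control profile) and "mean centering" (ratio
# against the average of treatment profiles sharing the same control
# condition). Replicates, doses and collapsed sub-times are averaged into a
# single signature per (compound, cell line).

#' Center and scale a signature vector
#'
#' Centers to mean zero and scales to standard deviation one, using the
#' population standard deviation (denominator `d`). A constant input has no
#' scale; it is returned as the all-zero vector with attribute
#' `degenerate = TRUE` rather than raising an error, and downstream
#' similarity search excludes such signatures.
#'
#' @param v numeric vector, length >= 2, finite.
#' @return standardized vector with a logical `degenerate` attribute.
#' @export
#' @examples
#' standardize(c(1, 2, 3))
standardize <- function(v) {
  if (length(v) < 2L) abort("standardize: need at least 2 values")
  if (!all(is.finite(v))) abort("standardize: non-finite input")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) {
    out <- numeric(length(v))
    names(out) <- names(v)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (v - m) / s
  attr(out, "degenerate") <- FALSE
  out
}

is_degenerate <- function(v) isTRUE(attr(v, "degenerate"))

log_ratio <- function(num, den, log_base, epsilon) {
  if (epsilon <= 0) abort("epsilon must be > 0")
  log(pmax(num, epsilon) / pmax(den, epsilon), base = log_base)
}

#' Build one signature under biological-control normalization
#'
#' Per-gene log ratio of the treatment profile to its matched control
#' profile, then standardized. Expression values are floored at `epsilon`
#' before the ratio so zero counts stay finite.
#'
#' @param treatment,control numeric profiles sharing gene order.
#' @param log_base logarithm base (default 2; immaterial after
#'   standardization since Pearson correlation is scale-invariant).
#' @param epsilon positive floor applied to both profiles (default 0.01).
#' @return standardized signature vector with `degenerate` attribute.
#' @export
signature_biological_control <- function(treatment, control, log_base = 2, epsilon = 0.01) {
  if (length(treatment) != length(control)) {
    abort("signature_biological_control: treatment and control lengths differ (%d vs %d)",
          length(treatment), length(control))
  }
  standardize(log_ratio(treatment, control, log_base, epsilon))
}

#' Build one signature under mean-centering normalization
#'
#' The control profile is the per-gene arithmetic mean of all treatment
#' profiles measured under the same biological control condition (the
#' "averaged control profile"); the signature is the log ratio of the target
#' profile to that average, standardized.
#'
#' @param group genes-by-profiles matrix of all treatment profiles in one
#'   control-condition group, including the target (>= 2 profiles).
#' @param target the profile to build a signature for.
#' @inheritParams signature_biological_control
#' @return standardized signature vector with `degenerate` attribute.
#' @export
signature_mean_centering <- function(group, target, log_base = 2, epsilon = 0.01) {
  group <- as.matrix(group)
  if (ncol(group) < 2L) abort("signature_mean_centering: group must contain >= 2 profiles")
  if (nrow(group) != length(target)) abort("signature_mean_centering: gene order mismatch")
  avg_control <- rowMeans(group)
  standardize(log_ratio(target, avg_control, log_base, epsilon))
}

#' Average replicate signatures
#'
#' Element-wise arithmetic mean of signatures for one (compound, cell line),
#' re-standardized so the integrated signature again has mean zero and unit
#' standard deviation (re-standardization does not change any Pearson
#' correlation involving the signature).
#'
#' @param sigs list of signature vectors with identical gene order.
#' @return averaged, re-standardized signature; attribute
#'   `n_source_profiles` records the count.
#' @export
average_signatures <- function(sigs) {
  if (!length(sigs)) abort("average_signatures: empty input")
  d <- unique(lengths(sigs))
  if (length(d) != 1L) abort("average_signatures: signatures differ in length")
  out <- standardize(rowMeans(matrix(unlist(sigs), nrow = d)))
  names(out) <- names(sigs[[1L]])
  attr(out, "n_source_profiles") <- length(sigs)
  out
}

#' Collapse measurement sub-times to canonical time buckets
#'
#' Profiles measured at 6.4 h and 24.4 h are regarded as 6 h and 24 h
#' respectively; all other times pass through unchanged.
#'
#' @param time_h numeric vector of hours (> 0).
#' @return canonical times.
#' @export
#' @examples
#' collapse_time(c(6, 6.4, 24.4, 48))
collapse_time <- function(time_h) {
  out <- time_h
  out[out == 6.4] <- 6
  out[out == 24.4] <- 24
  out
}

parse_selection <- function(select) {
  if (is.numeric(select)) return(as.integer(select))
  switch(select,
         all = NULL,
         top50 = 50L,
         top100 = 100L,
         {
           if (grepl("^top:[0-9]+$", select)) as.integer(sub("^top:", "", select))
           else abort("unknown selection preset '%s' (use all, top50, top100 or top:<k>)", select)
         })
}

#' Keep only the top and bottom ranked genes of a signature
#'
#' Retains the `k` largest and `k` smallest entries and sets all remaining
#' entries to zero, the rationale being that small expression ratios are
#' mostly noise. Presets `"top50"`, `"top100"` and `"all"` are supported;
#' `"all"` returns the input unchanged. Ties are broken stably by gene index
#' (the top block is filled first, the bottom block from the remaining
#' entries), so the output has exactly `2k` non-zeros.
#'
#' @param sig signature vector.
#' @param select `"all"`, `"top50"`, `"top100"`, `"top:<k>"`, or an integer k.
#' @return signature with all but the 2k extreme entries zeroed.
#' @export
select_top_bottom <- function(sig, select) {
  k <- parse_selection(select)
  if (is.null(k)) return(sig)
  d <- length(sig)
  if (k <= 0 || 2L * k > d) abort("select_top_bottom: need 0 < k <= d/2 (k=%d, d=%d)", k, d)
  idx <- seq_len(d)
  top <- idx[order(-sig, idx)][seq_len(k)]
  rest <- setdiff(idx, top)
  bottom <- rest[order(sig[rest], rest)][seq_len(k)]
  out <- numeric(d)
  names(out) <- names(sig)
  keep <- c(top, bottom)
  out[keep] <- sig[keep]
  attr(out, "degenerate") <- attr(sig, "degenerate") %||% FALSE
  out
}

#' Construct a signature set
#'
#' @param values genes-by-signatures numeric matrix; columns keyed
#'   `compound|cell_line`.
#' @param keys data.frame with columns `compound_id`, `cell_line`, `time_h`,
#'   `n_source_profiles`, `degenerate`, one row per column of `values`.
#' @return object of class `signature_set`.
#' @export
signature_set <- function(values, keys) {
  stopifnot(is.matrix(values), nrow(keys) == ncol(values))
  need <- c("compound_id", "cell_line", "time_h", "n_source_profiles", "degenerate")
  missing <- setdiff(need, names(keys))
  if (length(missing)) abort("signature_set keys: missing column(s) %s", paste(missing, collapse = ", "))
  key <- paste(keys$compound_id, keys$cell_line, sep = "|")
  if (anyDuplicated(key)) abort("signature_set: duplicate (compound, cell line) key '%s'", key[duplicated(key)][1L])
  o <- order(keys$compound_id, keys$cell_line)
  values <- values[, o, drop = FALSE]
  keys <- keys[o, , drop = FALSE]
  rownames(keys) <- NULL
  colnames(values) <- key[o]
  structure(list(values = values, keys = keys, gene_ids = rownames(values)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d genes x %d signatures (%d compounds, %d cell lines, %d degenerate)\n",
              nrow(x$values), ncol(x$values), length(unique(x$keys$compound_id)),
              length(unique(x$keys$cell_line)), sum(x$keys$degenerate)))
  invisible(x)
}

#' Signatures of one compound across cell lines
#'
#' @param set a `signature_set`.
#' @param compound compound id.
#' @param drop_degenerate exclude constant (all-zero) signatures, which carry
#'   no correlation information (default TRUE).
#' @return genes-by-cells matrix with cell-line column names.
#' @export
signature_group <- function(set, compound, drop_degenerate = TRUE) {
  sel <- set$keys$compound_id == compound
  if (drop_degenerate) sel <- sel & !set$keys$degenerate
  m <- set$values[, sel, drop = FALSE]
  colnames(m) <- set$keys$cell_line[sel]
  m
}

#' Build all signatures from an expression matrix and metadata
#'
#' Orchestrates signature construction: profiles at the requested canonical
#' time (after collapsing 6.4 h to 6 h and 24.4 h to 24 h) are converted to
#' per-profile standardized log-ratio signatures under the chosen
#' normalization, then averaged within each (compound, cell line) and
#' re-standardized, then optionally masked to the top/bottom ranked genes.
#'
#' Under biological-control normalization, treatments whose `control_ref`
#' does not resolve are skipped with a warning. Under mean-centering
#' normalization the control-condition group is the set of treatment
#' profiles sharing (`cell_line`, `control_ref`); groups of size 1 are
#' skipped (no population to average).
#'
#' @param mat genes-by-samples expression matrix (linear scale).
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @param method `"biological_control"` or `"mean_centering"`.
#' @param time_filter canonical time in hours to keep (default 6; `NULL`
#'   keeps all times and averages across them).
#' @param select gene selection preset passed to [select_top_bottom()].
#' @inheritParams signature_biological_control
#' @return a `signature_set`.
#' @export
build_signature_set <- function(mat, meta,
                                method = c("biological_control", "mean_centering"),
                                log_base = 2, epsilon = 0.01,
                                time_filter = 6, select = "all") {
  method <- match.arg(method)
  validate_expression_matrix(mat)
  # unresolvable control_refs are skipped (with a warning) below, not fatal
  validate_sample_metadata(meta, check_refs = FALSE)
  missing <- setdiff(meta$sample_id, colnames(mat))
  if (length(missing)) abort("metadata sample '%s' absent from expression matrix", missing[1L])

  trt <- meta[meta$role == "treatment", , drop = FALSE]
  trt$ctime <- collapse_time(trt$time_h)
  if (!is.null(time_filter)) trt <- trt[trt$ctime == time_filter, , drop = FALSE]
  if (!nrow(trt)) abort("no treatment profiles at the requested time")

  # per-profile standardized log-ratio signatures
  sigs <- vector("list", nrow(trt))
  keep <- logical(nrow(trt))
  if (method == "biological_control") {
    ok <- nzchar(trt$control_ref) & trt$control_ref %in% colnames(mat)
    if (any(!ok)) {
      warning(sprintf("skipping %d treatment profile(s) with unresolvable control_ref", sum(!ok)))
    }
    for (i in which(ok)) {
      sigs[[i]] <- signature_biological_control(mat[, trt$sample_id[i]], mat[, trt$control_ref[i]],
                                                log_base, epsilon)
      keep[i] <- TRUE
    }
  } else {
    grp_key <- paste(trt$cell_line, trt$control_ref, sep = "\r")
    for (g in unique(grp_key)) {
      members <- which(grp_key == g)
      if (length(members) < 2L) {
        warning(sprintf("skipping control-condition group of size 1 (cell line %s)",
                        trt$cell_line[members[1L]]))
        next
      }
      grp_mat <- mat[, trt$sample_id[members], drop = FALSE]
      for (i in members) {
        sigs[[i]] <- signature_mean_centering(grp_mat, mat[, trt$sample_id[i]], log_base, epsilon)
        keep[i] <- TRUE
      }
    }
  }
  if (!any(keep)) abort("no signatures could be constructed")

  trt <- trt[keep, , drop = FALSE]
  sigs <- sigs[keep]
  cmp_key <- paste(trt$compound_id, trt$cell_line, sep = "\r")
  ukeys <- unique(cmp_key)
  d <- nrow(mat)
  values <- matrix(0, nrow = d, ncol = length(ukeys))
  rownames(values) <- rownames(mat)
  keys <- data.frame(compound_id = character(length(ukeys)), cell_line = "",
                     time_h = 0, n_source_profiles = 0L, degenerate = FALSE,
                     stringsAsFactors = FALSE)
  for (j in seq_along(ukeys)) {
    members <- which(cmp_key == ukeys[j])
    avg <- average_signatures(sigs[members])
    avg <- select_top_bottom(avg, select)
    values[, j] <- avg
    keys$compound_id[j] <- trt$compound_id[members[1L]]
    keys$cell_line[j] <- trt$cell_line[members[1L]]
    keys$time_h[j] <- trt$ctime[members[1L]]
    keys$n_source_profiles[j] <- length(members)
    keys$degenerate[j] <- is_degenerate(avg)
  }
  signature_set(values, keys)
}
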