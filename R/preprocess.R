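#' Log2-transform raw intensities
#'
#' Element-wise `log2(raw + offset)`. Every shifted value must be strictly
#' positive; the first offending cell is named in the error.
#'
#' @param raw nonnegative numeric matrix (probes x samples) or `expr_mat`.
#' @param offset nonnegative shift added before taking logs (default 0).
#' @param probe_to_gene optional annotation when `raw` is a bare matrix.
#' @return An `expr_mat` on log2 scale; annotation is preserved.
#' @export
log2_transform <- function(raw, offset = 0, probe_to_gene = NULL) {
  if (inherits(raw, "expr_mat")) {
    if (is.null(probe_to_gene)) probe_to_gene <- raw$probe_to_gene
    raw <- raw$values
  }
  if (offset < 0) stop("`offset` must be nonnegative")
  shifted <- raw + offset
  bad <- which(shifted <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-positive value after offset at probe '%s', sample '%s' (%g)",
      rownames(raw)[bad[1, 1]], colnames(raw)[bad[1, 2]],
      shifted[bad[1, 1], bad[1, 2]]))
  }
  expr_matrix(log2(shifted), probe_to_gene = probe_to_gene)
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the rank-wise mean of the sorted columns. Ties within a column receive
#' the mean of the tied ranks' reference values. With a single sample the
#' input is returned unchanged with a warning.
#'
#' @param expr an `expr_mat` (log2 scale expected but not enforced).
#' @return An `expr_mat` of the same shape.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "expr_mat"))
  if (ncol(expr$values) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(expr)
  }
  v <- limma::normalizeQuantiles(expr$values, ties = TRUE)
  dimnames(v) <- dimnames(expr$values)
  expr_matrix(v, probe_to_gene = expr$probe_to_gene)
}

#' Collapse probes to genes by coefficient of variation
#'
#' For each annotated gene keeps the most informative probe: the one with
#' the largest coefficient of variation, defined as the per-probe sample
#' standard deviation divided by the per-probe mean. Probes without gene
#' annotation are dropped. Genes for which no probe has a defined CV
#' (zero mean) are excluded with a warning.
#'
#' @param expr an `expr_mat` with `probe_to_gene` populated.
#' @return An `expr_mat` with one row per gene (row names are gene symbols);
#'   the winning probe for each gene is recorded in the `gene_to_probe`
#'   attribute and in `probe_to_gene` (identity map gene -> gene).
#' @export
collapse_probes_by_cv <- function(expr) {
  stopifnot(inherits(expr, "expr_mat"))
  if (is.null(expr$probe_to_gene) || length(expr$probe_to_gene) == 0)
    stop("`probe_to_gene` annotation is required to collapse probes")
  ann <- expr$probe_to_gene
  v <- expr$values[names(ann), , drop = FALSE]
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu)
  keep <- !is.na(cv)
  dropped_genes <- setdiff(unique(ann[!keep]), unique(ann[keep]))
  if (length(dropped_genes) > 0)
    warning(sprintf("excluding %d gene(s) with undefined CV (zero mean): %s",
                    length(dropped_genes),
                    paste(dropped_genes, collapse = ", ")))
  ann <- ann[keep]; cv <- cv[keep]
  ord <- order(ann, -cv, names(ann))       # deterministic winner per gene
  ann <- ann[ord]; winners <- names(ann)[!duplicated(ann)]
  genes <- ann[!duplicated(ann)]
  out <- expr$values[winners, , drop = FALSE]
  rownames(out) <- unname(genes)
  res <- expr_matrix(out,
                     probe_to_gene = stats::setNames(unname(genes), unname(genes)))
  attr(res, "gene_to_probe") <- stats::setNames(winners, unname(genes))
  res
}

#' Per-probe z-standardization
#'
#' Subtracts each probe's sample mean and divides by its sample standard
#' deviation (n - 1 denominator). Probes with zero variance are mapped to
#' all-zero rows with a warning.
#'
#' @param expr an `expr_mat` with at least 2 samples.
#' @return An `expr_mat` whose rows have mean 0 and sd 1 (or are all zero),
#'   flagged with attribute `standardized = TRUE`.
#' @export
z_transform <- function(expr) {
  stopifnot(inherits(expr, "expr_mat"))
  if (ncol(expr$values) < 2) stop("z-transform needs >= 2 samples")
  mu <- rowMeans(expr$values)
  sdv <- apply(expr$values, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sprintf("%d zero-variance probe(s) set to all-zero z-rows",
                    sum(flat)))
    sdv[flat] <- 1
  }
  z <- (expr$values - mu) / sdv
  z[flat, ] <- 0
  res <- expr_matrix(z, probe_to_gene = expr$probe_to_gene)
  attr(res, "standardized") <- TRUE
  res
}
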