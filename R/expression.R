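#' Expression matrix container
#'
#' A light container for a probes x samples matrix of (usually log2-scale)
#' expression values, together with an optional probe-to-gene annotation.
#' Row names are probe identifiers, column names are sample identifiers;
#' both must be unique.
#'
#' @param values numeric matrix, probes in rows and samples in columns, with
#'   unique row and column names.
#' @param probe_to_gene optional named character vector mapping probe ids to
#'   gene symbols. Probes absent from the map are treated as unannotated.
#' @return An object of class `expr_mat` with elements `values` and
#'   `probe_to_gene`.
#' @export
expr_matrix <- function(values, probe_to_gene = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (probes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (!is.null(probe_to_gene)) {
    if (is.null(names(probe_to_gene)))
      stop("`probe_to_gene` must be a named character vector")
    probe_to_gene <- probe_to_gene[names(probe_to_gene) %in% rownames(values)]
  }
  structure(list(values = values, probe_to_gene = probe_to_gene),
            class = "expr_mat")
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d probes x %d samples (%s annotation)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$probe_to_gene)) "no" else
                sprintf("%d probes with", length(x$probe_to_gene))))
  invisible(x)
}

probe_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a probes x samples expression TSV
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Lines starting with `!` (GEO series-matrix style comments) are skipped,
#' as are the `ID_REF` header variants GEO emits.
#'
#' @param path path to a tab-separated file.
#' @param probe_to_gene optional annotation passed through to [expr_matrix()].
#' @return An `expr_mat`.
#' @export
read_expression_tsv <- function(path, probe_to_gene = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "!",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  expr_matrix(m, probe_to_gene = probe_to_gene)
}

#' Write an expression matrix as TSV
#'
#' The inverse of [read_expression_tsv()]: first column `probe_id`, then one
#' column per sample.
#'
#' @param x an `expr_mat`.
#' @param path output path.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(probe_id = probe_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column probe-to-gene annotation TSV
#'
#' @param path file with columns `probe_id` and `gene` (header required).
#' @return Named character vector, probe id -> gene symbol.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "!",
                          stringsAsFactors = FALSE, quote = "\"")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

gene_of <- function(x, probes) {
  if (is.null(x$probe_to_gene)) return(rep(NA_character_, length(probes)))
  unname(x$probe_to_gene[probes])
}
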