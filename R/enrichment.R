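#' Rank genes by differential-expression significance
#'
#' Orders every row of the matrix by the signed pooled-variance t statistic
#' between two sample groups, descending: rows up-regulated in the first
#' group come first. This is the ranked profile a running-sum enrichment
#' walks over.
#'
#' @param expr an `expr_mat` (probe- or gene-level).
#' @param group_a,group_b disjoint sample-id vectors (>= 2 each); the sign
#'   convention is "up in `group_a` at the top".
#' @return A data.frame `id`, `metric` sorted by decreasing metric.
#' @export
rank_genes <- function(expr, group_a, group_b) {
  de <- differential_expression(expr, group_a, group_b)
  out <- data.frame(id = de$probe_id, metric = de$t,
                    stringsAsFactors = FALSE)
  out[order(-out$metric, out$id), , drop = FALSE]
}

#' Running-sum enrichment score
#'
#' Weighted Kolmogorov-Smirnov-like statistic: walking down the ranked
#' list, the running sum rises by `|metric|^p / sum(|metric|^p over set
#' hits)` at gene-set members and falls by `1 / (N - Nh)` elsewhere. The
#' enrichment score (ES) is the signed extremum of the walk; the leading
#' edge is the set members at or before the extremum (at or after it for a
#' negative ES). With `p = 0` this reduces to the classic unweighted KS
#' statistic.
#'
#' @param ranked data.frame from [rank_genes()] (columns `id`, `metric`,
#'   already sorted), or a named numeric vector of metrics sorted
#'   decreasingly.
#' @param gene_set character vector; must intersect the ranked ids.
#' @param p hit-weight exponent (default 1, standard GSEA weighting).
#' @return List of class `enrichment_result`: `es`, `running_sum` (length
#'   N, starts and ends at 0 increments), `leading_edge`, `hits` (logical
#'   over ranks).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  if (is.numeric(ranked) && !is.null(names(ranked)))
    ranked <- data.frame(id = names(ranked), metric = unname(ranked),
                         stringsAsFactors = FALSE)
  ids <- ranked$id; metric <- ranked$metric
  n <- length(ids)
  hits <- ids %in% gene_set
  nh <- sum(hits)
  if (nh == 0) stop("gene set does not intersect the ranked list")
  if (nh == n) stop("gene set covers the whole ranked list")
  w <- abs(metric)^p
  wh <- sum(w[hits])
  if (wh == 0) { w <- rep(1, n); wh <- nh }  # all-zero hit metrics: fall back to unweighted
  step <- ifelse(hits, w / wh, -1 / (n - nh))
  rs <- cumsum(step)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  leading <- if (es >= 0) ids[hits & seq_len(n) <= i_ext]
             else ids[hits & seq_len(n) >= i_ext]
  structure(list(es = es, running_sum = rs, leading_edge = leading,
                 hits = hits),
            class = "enrichment_result")
}

#' Gene-permutation significance of an enrichment score
#'
#' Null distribution built by drawing random gene sets of the observed size
#' from the ranked universe (gene permutation, not phenotype permutation).
#' By default the P-value is one-sided on the observed ES sign: the
#' fraction of null ES at least as extreme in that direction. Set
#' `alternative = "two.sided"` to compare |null| against |observed|.
#'
#' @param ranked as in [enrichment_score()].
#' @param gene_set character vector.
#' @param n_perm number of random sets (default 2000).
#' @param seed RNG seed; mandatory.
#' @param p hit-weight exponent (default 1).
#' @param alternative "one.sided" (default) or "two.sided".
#' @return An `enrichment_result` with `empirical_p`, `p_label`, `n_perm`,
#'   and `null_es` added.
#' @export
enrichment_p <- function(ranked, gene_set, n_perm = 2000, seed, p = 1,
                         alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("`seed` is mandatory")
  if (is.numeric(ranked) && !is.null(names(ranked)))
    ranked <- data.frame(id = names(ranked), metric = unname(ranked),
                         stringsAsFactors = FALSE)
  obs <- enrichment_score(ranked, gene_set, p = p)
  k <- sum(obs$hits)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    rnd <- sample(ranked$id, k)
    enrichment_score(ranked, rnd, p = p)$es
  }, numeric(1))
  ep <- switch(alternative,
    one.sided = if (obs$es >= 0) mean(null_es >= obs$es)
                else mean(null_es <= obs$es),
    two.sided = mean(abs(null_es) >= abs(obs$es)))
  obs$empirical_p <- ep
  obs$p_label <- if (ep == 0) sprintf("< %.3g", 1 / n_perm) else format(ep)
  obs$n_perm <- n_perm
  obs$null_es <- null_es
  obs
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write enrichment results as TSV
#'
#' One row per gene set: set, size, ES, empirical P, leading-edge genes
#' (comma-separated).
#'
#' @param results named list of `enrichment_result`s (from
#'   [enrichment_p()]).
#' @param path output path.
#' @export
write_enrichment_tsv <- function(results, path) {
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(set = nm, size = sum(r$hits), es = r$es,
               empirical_p = if (is.null(r$empirical_p)) NA_real_
                             else r$empirical_p,
               leading_edge = paste(r$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
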