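#' Equal-weight z-score risk score
#'
#' A patient's risk score is the unweighted sum of their z-values over the
#' signature rows: every signature member contributes with unit weight.
#' Because each z-row has zero mean, the cohort mean of the scores is ~0.
#'
#' @param zexpr z-standardized `expr_mat`; rows must resolve the signature
#'   members (probe ids for probe-level matrices, gene symbols after
#'   [collapse_probes_by_cv()] + [map_signature()]).
#' @param signature a `cnaml_signature`, or a character vector of row ids.
#' @return A data.frame with `sample_id` and `score`.
#' @export
compute_risk_score <- function(zexpr, signature) {
  stopifnot(inherits(zexpr, "expr_mat"))
  ids <- if (is.character(signature)) signature else signature$probe_id
  ids <- intersect(ids, probe_ids(zexpr))
  if (length(ids) == 0)
    stop("no signature member resolvable in the expression matrix")
  sc <- colSums(zexpr$values[ids, , drop = FALSE])
  data.frame(sample_id = sample_ids(zexpr), score = unname(sc),
             stringsAsFactors = FALSE)
}

#' Median split of risk scores
#'
#' Scores strictly above the cohort median go to the "high" group, the rest
#' to "low"; for an even cohort with distinct scores this gives equal
#' halves. If every score ties the median all samples land in "low" with a
#' warning.
#'
#' @param scores data.frame from [compute_risk_score()].
#' @return The input with a `median_group` factor column (levels low, high).
#' @export
split_by_median <- function(scores) {
  if (nrow(scores) < 2) stop("median split needs >= 2 samples")
  med <- stats::median(scores$score)
  grp <- ifelse(scores$score > med, "high", "low")
  if (all(grp == "low"))
    warning("all scores tie the median; everyone assigned to the low group")
  scores$median_group <- factor(grp, levels = c("low", "high"))
  scores
}

#' Mean +/- k SD extreme groups
#'
#' Labels patients with scores above `mean + k_sd * sd` as high-risk and
#' below `mean - k_sd * sd` as low-risk; everyone else is "middle". Used for
#' the score-extremes differential-expression contrast.
#'
#' @param scores data.frame from [compute_risk_score()].
#' @param k_sd number of standard deviations defining the tails (default 1).
#' @return The input with an `extreme_group` factor column
#'   (levels low_risk, middle, high_risk).
#' @export
extreme_groups <- function(scores, k_sd = 1) {
  if (nrow(scores) < 3) stop("extreme grouping needs >= 3 samples")
  mu <- mean(scores$score); sdv <- stats::sd(scores$score)
  grp <- rep("middle", nrow(scores))
  grp[scores$score > mu + k_sd * sdv] <- "high_risk"
  grp[scores$score < mu - k_sd * sdv] <- "low_risk"
  scores$extreme_group <- factor(grp,
                                 levels = c("low_risk", "middle", "high_risk"))
  scores
}

#' Transfer a signature to another cohort by gene symbol
#'
#' Matches signature members to the rows of a gene-level expression matrix
#' (see [collapse_probes_by_cv()]). Matching is exact on the symbol — no
#' fuzzy or alias matching. Unmatched members are dropped with a warning;
#' zero matches is an error.
#'
#' @param signature a `cnaml_signature`.
#' @param target gene-level `expr_mat`.
#' @return The signature restricted to matched genes, with `probe_id`
#'   rewritten to the target's row ids (gene symbols).
#' @export
map_signature <- function(signature, target) {
  stopifnot(inherits(target, "expr_mat"))
  hit <- signature$gene %in% probe_ids(target)
  if (!any(hit))
    stop("no signature gene found in the target cohort")
  if (any(!hit))
    warning(sprintf("%d signature gene(s) absent from target, dropped: %s",
                    sum(!hit), paste(signature$gene[!hit], collapse = ", ")))
  out <- signature[hit, , drop = FALSE]
  out$probe_id <- out$gene
  rownames(out) <- NULL
  out
}

#' Write risk scores as CSV
#'
#' @param scores data.frame with `sample_id`, `score`, and any grouping
#'   columns already added.
#' @param path output path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
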