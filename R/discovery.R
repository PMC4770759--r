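#' Response-group differential expression
#'
#' Per-probe equal-variance (pooled) two-sided Student t-test between the
#' poor-response (PR, refractory to induction) and good-response (GR,
#' continuous complete remission) groups, on log2-scale values. A probe is
#' selected when `P < p_thresh` and the absolute log2 mean difference
#' exceeds `log2(fold_thresh)`.
#'
#' @param expr an `expr_mat` on log2 scale.
#' @param group_pr,group_gr disjoint character vectors of sample ids, each
#'   of size >= 2.
#' @param p_thresh t-test significance threshold (default 0.05).
#' @param fold_thresh fold-change threshold on natural scale (default 2,
#'   i.e. |delta log2| > 1).
#' @return A data.frame with one row per probe: `probe_id`, `gene`,
#'   `mean_pr`, `mean_gr`, `delta_log2`, `fold_change`, `t`, `p`,
#'   `direction` ("up"/"down" in PR), `selected`.
#' @export
differential_expression <- function(expr, group_pr, group_gr,
                                    p_thresh = 0.05, fold_thresh = 2) {
  stopifnot(inherits(expr, "expr_mat"))
  if (length(intersect(group_pr, group_gr)) > 0)
    stop("PR and GR groups overlap")
  if (length(group_pr) < 2 || length(group_gr) < 2)
    stop("each group needs >= 2 samples")
  missing <- setdiff(c(group_pr, group_gr), sample_ids(expr))
  if (length(missing) > 0)
    stop("samples not in expression matrix: ",
         paste(missing, collapse = ", "))

  x1 <- expr$values[, group_pr, drop = FALSE]
  x0 <- expr$values[, group_gr, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  delta <- m1 - m0
  tstat <- delta / se
  # zero-variance probes: no evidence against equality when means agree,
  # certain difference when they do not
  flat <- se == 0
  tstat[flat] <- ifelse(delta[flat] == 0, 0, sign(delta[flat]) * Inf)
  pval <- 2 * stats::pt(-abs(tstat), df = n1 + n0 - 2)
  data.frame(
    probe_id = probe_ids(expr),
    gene = gene_of(expr, probe_ids(expr)),
    mean_pr = m1, mean_gr = m0,
    delta_log2 = delta,
    fold_change = 2^abs(delta),
    t = tstat, p = pval,
    direction = ifelse(delta >= 0, "up", "down"),
    selected = pval < p_thresh & abs(delta) > log2(fold_thresh),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Survival filter of response-associated probes
#'
#' Second selection stage: for every probe selected by
#' [differential_expression()], fits a univariate Cox proportional-hazards
#' model of overall survival on the probe's z-values (Efron ties) and keeps
#' probes with Wald `P < p_thresh`. The clinical table should already be
#' restricted to the intensively treated patients. No multiple-testing
#' correction is applied at either stage; that mirrors the discovery design
#' this package implements and is deliberate.
#'
#' @param de output of [differential_expression()].
#' @param zexpr z-standardized `expr_mat` (see [z_transform()]).
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event` for
#'   the samples entering the survival filter.
#' @param p_thresh Wald significance threshold (default 0.01).
#' @return A data.frame of class `cnaml_signature`, one row per retained
#'   probe: `probe_id`, `gene`, `cox_p`, `hr`, `ci_low`, `ci_high`, plus the
#'   DE columns, ordered by probe id.
#' @export
cox_filter <- function(de, zexpr, clinical, p_thresh = 0.01) {
  stopifnot(inherits(zexpr, "expr_mat"))
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% names(clinical)))
    stop("clinical table must contain ", paste(need, collapse = ", "))
  if (anyNA(clinical$os_time) || anyNA(clinical$os_event))
    stop("survival columns must be complete")
  if (sum(clinical$os_event) < 2)
    stop("fewer than 2 events; cannot fit survival models")
  cand <- de$probe_id[de$selected]
  cand <- sort(cand)                       # probe/sample order invariance
  ids <- intersect(clinical$sample_id, sample_ids(zexpr))
  cl <- clinical[match(ids, clinical$sample_id), ]
  surv <- survival::Surv(cl$os_time, cl$os_event)
  rows <- lapply(cand, function(pb) {
    z <- zexpr$values[pb, ids]
    fit <- survival::coxph(surv ~ z, ties = "efron")
    s <- summary(fit)$coefficients
    data.frame(probe_id = pb, cox_p = s[1, "Pr(>|z|)"],
               hr = exp(s[1, "coef"]),
               ci_low = exp(s[1, "coef"] - 1.96 * s[1, "se(coef)"]),
               ci_high = exp(s[1, "coef"] + 1.96 * s[1, "se(coef)"]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res)) res <- data.frame(probe_id = character(), cox_p = numeric(),
                                      hr = numeric(), ci_low = numeric(),
                                      ci_high = numeric())
  res <- res[res$cox_p < p_thresh, , drop = FALSE]
  out <- merge(res, de, by = "probe_id", sort = TRUE)
  out <- out[order(out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnaml_signature", "data.frame")
  out
}

#' Write a signature table as TSV
#'
#' Columns mirror a published signature table: probe, gene, univariate Cox
#' P, hazard ratio and confidence bounds, plus the differential-expression
#' statistics.
#'
#' @param signature a `cnaml_signature`.
#' @param path output path.
#' @export
write_signature_tsv <- function(signature, path) {
  utils::write.table(as.data.frame(signature), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
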