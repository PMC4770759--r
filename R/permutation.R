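#' Random-gene-set permutation test of a scoring system
#'
#' The non-randomness check for an equal-weight z-score system: each
#' iteration substitutes the signature with the same number of probes drawn
#' uniformly without replacement from the full matrix, rebuilds the score,
#' and fits a univariate Cox model of overall survival on it. "Cox
#' significance" is the Wald P of the score coefficient (smaller = more
#' significant). The empirical P is the fraction of random systems strictly
#' more significant than the proposed one; random systems tying the
#' observed significance do not count as exceeding. Iterations whose Cox
#' fit fails are recorded as non-significant (P = 1) with a warning, which
#' is conservative. Sampling is at probe level from the supplied matrix.
#'
#' @param zexpr z-standardized `expr_mat` (the probe universe).
#' @param clinical clinical table for the samples entering the survival
#'   model (restrict to the intensively treated before calling).
#' @param signature a `cnaml_signature` or character vector of probe ids.
#' @param n_iter number of random systems (default 10000).
#' @param seed RNG seed; mandatory for reproducibility.
#' @return List of class `perm_result`: `observed_stat` (Wald P of the
#'   proposed score), `null_stats`, `empirical_p`, `p_label` (a
#'   "< 1/n_iter" style bound when no null exceeds), `n_iter`, `seed`.
#' @export
permutation_null <- function(zexpr, clinical, signature, n_iter = 10000,
                             seed) {
  stopifnot(inherits(zexpr, "expr_mat"), n_iter >= 1)
  if (missing(seed)) stop("`seed` is mandatory")
  k <- if (is.character(signature)) length(signature) else nrow(signature)
  p <- nrow(zexpr$values)
  if (k > p) stop("signature larger than the probe universe")

  ids <- intersect(clinical$sample_id, sample_ids(zexpr))
  cl <- clinical[match(ids, clinical$sample_id), ]
  surv <- survival::Surv(cl$os_time, cl$os_event)
  z <- zexpr$values[, ids, drop = FALSE]

  wald_p <- function(score) {
    tryCatch({
      fit <- survival::coxph(surv ~ score, ties = "efron")
      summary(fit)$coefficients[1, "Pr(>|z|)"]
    }, error = function(e) NA_real_)
  }

  obs_score <- compute_risk_score(zexpr, signature)
  observed <- wald_p(obs_score$score[match(ids, obs_score$sample_id)])
  if (is.na(observed)) stop("Cox fit of the proposed score failed")

  set.seed(seed)
  draws <- matrix(0L, k, n_iter)
  for (i in seq_len(n_iter)) draws[, i] <- sample.int(p, k)
  null_stats <- numeric(n_iter)
  n_fail <- 0L
  for (i in seq_len(n_iter)) {
    sc <- colSums(z[draws[, i], , drop = FALSE])
    pv <- wald_p(sc)
    if (is.na(pv)) { pv <- 1; n_fail <- n_fail + 1L }
    null_stats[i] <- pv
  }
  if (n_fail > 0)
    warning(sprintf("%d random system(s) failed to fit; recorded as P = 1",
                    n_fail))
  ep <- empirical_p(observed, null_stats)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 empirical_p = ep,
                 p_label = attr(ep, "label"),
                 n_iter = n_iter, seed = seed),
            class = "perm_result")
}

#' Empirical P from a permutation null
#'
#' Fraction of null statistics strictly more significant (smaller P) than
#' the observed one. When none exceeds, the value is 0 and a "< 1/n" bound
#' label accompanies it.
#'
#' @param observed observed significance statistic (a P-value; smaller =
#'   more significant).
#' @param null_stats non-empty numeric vector of null significances.
#' @return Numeric empirical P in \[0, 1\], with attribute `label` (e.g.
#'   "< 1.00e-04" when 0, otherwise the formatted fraction).
#' @export
empirical_p <- function(observed, null_stats) {
  if (length(null_stats) == 0) stop("null_stats must be non-empty")
  ep <- mean(null_stats < observed)
  label <- if (ep == 0) sprintf("< %.2e", 1 / length(null_stats))
           else format(ep)
  structure(ep, label = label)
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "<perm_result> observed Cox P = %.3g; empirical P %s (%d iterations, seed %s)\n",
    x$observed_stat,
    if (x$empirical_p == 0) x$p_label else sprintf("= %s", format(x$empirical_p)),
    x$n_iter, format(x$seed)))
  invisible(x)
}

#' Write a permutation null distribution as one-column TSV
#'
#' @param perm a `perm_result`.
#' @param path output path.
#' @export
write_null_tsv <- function(perm, path) {
  utils::write.table(data.frame(null_cox_p = perm$null_stats), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
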