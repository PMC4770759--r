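# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the survival package's fitting routines):
# brute-force or closed-form implementations small enough to be verified by
# reading them.

# Efron-approximation Cox partial log-likelihood for one covariate.
efron_loglik <- function(beta, time, status, x) {
  ll <- 0
  eta <- beta * x
  for (t in sort(unique(time[status == 1]))) {
    tied <- which(time == t & status == 1)
    risk <- which(time >= t)
    d <- length(tied)
    sum_risk <- sum(exp(eta[risk]))
    sum_tied <- sum(exp(eta[tied]))
    ll <- ll + sum(eta[tied])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_risk - (l / d) * sum_tied)
  }
  ll
}

# Maximize the Efron partial likelihood by coarse-then-fine grid search.
grid_cox_coef <- function(time, status, x, lim = 3) {
  coarse <- seq(-lim, lim, by = 0.01)
  ll <- vapply(coarse, efron_loglik, numeric(1), time, status, x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, efron_loglik, numeric(1), time, status, x)
  fine[which.max(llf)]
}

# Classic unweighted KS-style enrichment (p = 0): max-deviation of
# hit-fraction minus miss-fraction over prefixes.
ks_enrichment <- function(ids, gene_set) {
  hits <- ids %in% gene_set
  nh <- sum(hits); n <- length(ids)
  walk <- cumsum(ifelse(hits, 1 / nh, -1 / (n - nh)))
  walk[which.max(abs(walk))]
}

# A tiny expression fixture: named matrix wrapped as expr_mat.
make_expr <- function(values, genes = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  ann <- if (is.null(genes)) NULL else setNames(genes, rownames(values))
  expr_matrix(values, probe_to_gene = ann)
}
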