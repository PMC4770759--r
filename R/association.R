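#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square with 1 degree
#' of freedom — the variant that reproduces printed clinical-association
#' tables built from score-group contingency counts. Rows are the score
#' groups (low/high), columns feature present/absent.
#'
#' @param a,b,c,d the four counts, row-wise: `(a, b)` in the first group,
#'   `(c, d)` in the second. A single 2x2 matrix may be given as `a`.
#' @return List with `statistic` and two-sided `p`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  t <- as_2x2(a, b, c, d)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("chi-square undefined: a table margin is zero")
  ht <- stats::chisq.test(t, correct = FALSE)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided exact hypergeometric P (sum of tables with probability not
#' exceeding the observed one, at fixed margins). Used as the companion to
#' [chisq_2x2()] for sparse cells; both are reported, neither assumed
#' smaller.
#'
#' @inheritParams chisq_2x2
#' @return List with two-sided `p`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  t <- as_2x2(a, b, c, d)
  list(p = stats::fisher.test(t)$p.value)
}

as_2x2 <- function(a, b, c, d) {
  t <- if (is.matrix(a)) a else matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(t < 0) || any(t != round(t))) stop("counts must be nonnegative integers")
  if (sum(t) == 0) stop("empty table")
  t
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank-sum comparison of a continuous variable between two
#' groups; exact P for small untied samples, normal approximation with tie
#' correction otherwise. All-tied input returns P = 1 with a warning.
#'
#' @param values numeric vector.
#' @param groups two-level factor or vector of the same length.
#' @return List with `U` (statistic for the first group) and two-sided `p`.
#' @export
mann_whitney <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("exactly two groups required")
  g <- levels(droplevels(groups))
  x <- values[groups == g[1]]; y <- values[groups == g[2]]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (length(unique(values)) == 1) {
    warning("all values tied; P = 1")
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Score-group association report
#'
#' Builds a clinical/mutation association table for a median-split score:
#' binary variables get uncorrected Pearson chi-square and Fisher exact
#' P-values on the per-variable 2x2 counts (per-variable denominators —
#' rows with NA are excluded variable by variable); continuous variables
#' get a Mann-Whitney P and per-group medians.
#'
#' @param clinical clinical table with `sample_id`.
#' @param scores output of [split_by_median()].
#' @param binary_vars,continuous_vars column names to test.
#' @return A data.frame: `variable`, `type`, `n`, `n_low`, `n_high`,
#'   `stat_low`, `stat_high` (counts or medians), `p_chisq`, `p_fisher`,
#'   `p_ranksum`.
#' @export
association_table <- function(clinical, scores,
                              binary_vars = character(),
                              continuous_vars = character()) {
  d <- merge(clinical, scores[, c("sample_id", "median_group")],
             by = "sample_id")
  row_of <- function(variable, type, n, nl, nh, sl, sh, pc, pf, pr) {
    data.frame(variable = variable, type = type, n = n, n_low = nl,
               n_high = nh, stat_low = sl, stat_high = sh,
               p_chisq = pc, p_fisher = pf, p_ranksum = pr,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (v in binary_vars) {
    ok <- !is.na(d[[v]])
    x <- as.logical(d[[v]][ok]); g <- d$median_group[ok]
    a <- sum(x & g == "low");  b <- sum(!x & g == "low")
    cc <- sum(x & g == "high"); dd <- sum(!x & g == "high")
    pc <- tryCatch(chisq_2x2(a, b, cc, dd)$p, error = function(e) NA_real_)
    pf <- fisher_2x2(a, b, cc, dd)$p
    out[[v]] <- row_of(v, "binary", sum(ok), a + b, cc + dd, a, cc,
                       pc, pf, NA_real_)
  }
  for (v in continuous_vars) {
    ok <- !is.na(d[[v]])
    mw <- mann_whitney(d[[v]][ok], d$median_group[ok])
    out[[v]] <- row_of(v, "continuous", sum(ok),
                       sum(d$median_group[ok] == "low"),
                       sum(d$median_group[ok] == "high"),
                       stats::median(d[[v]][ok & d$median_group == "low"]),
                       stats::median(d[[v]][ok & d$median_group == "high"]),
                       NA_real_, NA_real_, mw$p)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}
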