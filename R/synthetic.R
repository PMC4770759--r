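#' Configuration for a synthetic CN-AML-like cohort
#'
#' The generator plants a single latent prognostic factor `r ~ N(0, 1)` per
#' patient. A block of co-expressed signature probes reads
#' `x = a + loading * r + noise`; the same factor drives the hazard of death
#' (`h0 * exp(beta * r)`), the probability of refractoriness to induction
#' chemotherapy (a logit in `r`), and mutation covariates. This mirrors the
#' structure the discovery analysis assumes: a transcriptional programme
#' jointly associated with treatment response and survival.
#'
#' @param n_samples cohort size (default 160).
#' @param n_probes probe universe size (default 5000).
#' @param n_signature number of planted signature probes, one per gene
#'   (default 11).
#' @param signature_loading per-probe coefficient on the latent factor
#'   (default 1.0, log2 units per latent SD).
#' @param baseline_hazard exponential baseline hazard, events per month
#'   (default 0.03).
#' @param log_hazard_coeff effect of the latent factor on the log hazard
#'   (default 0.7).
#' @param censor_horizon administrative follow-up horizon in months;
#'   censoring times are uniform on (0, horizon) (default 60).
#' @param response_intercept,response_slope logit coefficients for the
#'   probability of poor response (refractory, PR) among intensively treated
#'   patients: `P(PR) = plogis(intercept + slope * r)`. Defaults (-2.8, 4)
#'   give about a quarter of treated patients refractory, with a latent-factor
#'   separation between response groups of about 1.5 SD.
#' @param treated_fraction fraction receiving standard intensive
#'   chemotherapy (default 0.66); the rest are palliative and excluded from
#'   survival analyses.
#' @param hsct_rate fraction of treated patients receiving allogeneic stem
#'   cell transplant (default 0; transplant times are uniform within each
#'   patient's follow-up).
#' @param mutation_spec named list of `c(base_rate, score_logit_slope)` pairs;
#'   each flag is Bernoulli with `plogis(qlogis(base) + slope * r)`.
#' @param multiprobe_fraction fraction of genes represented by two probes
#'   (default 0.2).
#' @param signature_probes optional character vector of probe ids to plant
#'   the signature on (must be single-probe genes); by default the probes
#'   are drawn at random. Fixing them lets a validation cohort share the
#'   discovery cohort's planted genes, emulating signature transfer.
#' @param seed integer RNG seed; mandatory for reproducible cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 160,
                          n_probes = 5000,
                          n_signature = 11,
                          signature_loading = 1.0,
                          baseline_hazard = 0.03,
                          log_hazard_coeff = 0.7,
                          censor_horizon = 60,
                          response_intercept = -2.8,
                          response_slope = 4,
                          treated_fraction = 0.66,
                          hsct_rate = 0,
                          mutation_spec = list(
                            NPM1     = c(0.49, -0.8),
                            FLT3_ITD = c(0.33, 0.7),
                            ASXL1    = c(0.13, 1.2),
                            TET2     = c(0.20, 0.0),
                            DNMT3A   = c(0.26, 0.8),
                            CEBPA    = c(0.19, -1.5)),
                          multiprobe_fraction = 0.2,
                          signature_probes = NULL,
                          seed = 1L) {
  if (n_samples < 4 || n_probes < 2 || n_signature < 1)
    stop("non-positive or degenerate dimensions in cohort configuration")
  if (n_signature >= n_probes)
    stop("n_signature must be smaller than n_probes")
  if (censor_horizon <= 0) stop("censor_horizon must be positive")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (treated_fraction <= 0 || treated_fraction > 1)
    stop("treated_fraction must be in (0, 1]")
  if (hsct_rate < 0 || hsct_rate > 1) stop("hsct_rate must be in [0, 1]")
  for (m in mutation_spec)
    if (m[1] <= 0 || m[1] >= 1) stop("mutation base rates must be in (0, 1)")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws expression, survival, treatment-response, and mutation data under
#' the one-factor model described in [cohort_config()]. Expression values
#' are on log2 scale: signature probes are `a_g + b * r + e` with unit
#' Gaussian noise; the remaining probes are independent Gaussians with
#' probe-specific means and standard deviations drawn once per cohort.
#' Event times are exponential with hazard `h0 * exp(beta * r)`; follow-up
#' is censored at a uniform time on (0, horizon). Output is bit-identical
#' across runs for a fixed seed.
#'
#' @param config a [cohort_config()].
#' @return A list with elements
#'   * `expr`: an [expr_matrix()] of log2 expression,
#'   * `clinical`: a data.frame with `sample_id`, `os_time`, `os_event`,
#'     `dfs_time`, `dfs_event`, `response` (PR/GR/other),
#'     `treated_intensively`, `hsct_time`, `age`, `wbc`, `eln_favorable`,
#'     and one logical column per mutation,
#'   * `truth`: latent factor, planted probe ids, true log-hazard
#'     coefficient.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_samples; p <- cf$n_probes; k <- cf$n_signature

  samples <- sprintf("S%03d", seq_len(n))
  probes <- sprintf("probe_%05d", seq_len(p))

  # probe -> gene map: a fraction of genes carry two probes
  n_genes <- floor(p / (1 + cf$multiprobe_fraction))
  n_multi <- p - n_genes                       # genes with a second probe
  gene_idx <- c(seq_len(n_genes), seq_len(n_multi))
  genes <- sprintf("G%05d", gene_idx)
  probe_to_gene <- stats::setNames(genes, probes)

  # latent prognostic factor
  r <- stats::rnorm(n)

  # expression: probe-specific baselines, then overwrite the planted block
  base_mean <- stats::rnorm(p, mean = 8, sd = 1.5)
  base_sd <- stats::runif(p, 0.6, 1.4)
  x <- matrix(stats::rnorm(p * n, mean = base_mean, sd = base_sd), p, n)
  # plant on single-probe genes so the k probes map to k distinct genes
  single_probe <- probes[seq(n_multi + 1, n_genes)]
  if (is.null(cf$signature_probes)) {
    sig_probes <- sort(sample(single_probe, k))
  } else {
    if (!all(cf$signature_probes %in% single_probe))
      stop("signature_probes must name single-probe genes in the universe")
    if (length(cf$signature_probes) != k)
      stop("signature_probes must have length n_signature")
    sig_probes <- sort(cf$signature_probes)
  }
  sig_i <- match(sig_probes, probes)
  x[sig_i, ] <- base_mean[sig_i] +
    cf$signature_loading * outer(rep(1, k), r) +
    matrix(stats::rnorm(k * n), k, n)
  dimnames(x) <- list(probes, samples)

  # survival: exponential event times, uniform censoring
  haz <- cf$baseline_hazard * exp(cf$log_hazard_coeff * r)
  t_event <- stats::rexp(n, rate = haz)
  t_cens <- stats::runif(n, 0, cf$censor_horizon)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  t_rel <- stats::rexp(n, rate = 1.5 * haz)    # relapse/death composite
  t_cens2 <- stats::runif(n, 0, cf$censor_horizon)
  dfs_time <- pmin(t_rel, t_cens2)
  dfs_event <- as.integer(t_rel <= t_cens2)

  # treatment arm and induction response among the treated
  treated <- rep(FALSE, n)
  treated[sample.int(n, round(cf$treated_fraction * n))] <- TRUE
  p_pr <- stats::plogis(cf$response_intercept + cf$response_slope * r)
  is_pr <- treated & (stats::runif(n) < p_pr)
  response <- ifelse(!treated, "other", ifelse(is_pr, "PR", "GR"))

  hsct_time <- rep(NA_real_, n)
  if (cf$hsct_rate > 0) {
    cand <- which(treated & stats::runif(n) < cf$hsct_rate)
    hsct_time[cand] <- stats::runif(length(cand)) * os_time[cand]
  }

  clinical <- data.frame(
    sample_id = samples,
    os_time = os_time, os_event = os_event,
    dfs_time = dfs_time, dfs_event = dfs_event,
    response = response,
    treated_intensively = treated,
    hsct_time = hsct_time,
    age = pmin(90, pmax(16, round(55 + 4 * r + stats::rnorm(n, 0, 13)))),
    wbc = exp(3.3 - 0.3 * r + stats::rnorm(n, 0, 1)),
    eln_favorable = stats::runif(n) < stats::plogis(-0.2 - 0.6 * r),
    stringsAsFactors = FALSE)
  for (nm in names(cf$mutation_spec)) {
    sp <- cf$mutation_spec[[nm]]
    clinical[[nm]] <- stats::runif(n) <
      stats::plogis(stats::qlogis(sp[1]) + sp[2] * r)
  }

  list(expr = expr_matrix(x, probe_to_gene = probe_to_gene),
       clinical = clinical,
       truth = list(latent_factor = stats::setNames(r, samples),
                    signature_probe_ids = sig_probes,
                    true_log_hazard_coeff = cf$log_hazard_coeff))
}

#' Write a synthetic cohort to disk
#'
#' Emits the expression TSV (re-readable by [read_expression_tsv()]), the
#' probe annotation TSV, and the clinical CSV.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pe <- file.path(dir, "expression.tsv")
  pa <- file.path(dir, "annotation.tsv")
  pc <- file.path(dir, "clinical.csv")
  write_expression_tsv(cohort$expr, pe)
  utils::write.table(
    data.frame(probe_id = names(cohort$expr$probe_to_gene),
               gene = unname(cohort$expr$probe_to_gene)),
    pa, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$clinical, pc, row.names = FALSE)
  invisible(c(expression = pe, annotation = pa, clinical = pc))
}
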