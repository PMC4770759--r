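#' Pipeline configuration
#'
#' Bundles the thresholds and iteration counts of the end-to-end discovery
#' run. One master seed fans out to fixed per-stage seeds (cohort = seed,
#' permutation = seed + 1, enrichment = seed + 2).
#'
#' @param cohort_config a [cohort_config()] for synthetic input (its seed
#'   is overwritten by `seed`).
#' @param de_p,fold,cox_p discovery thresholds (defaults 0.05, 2, 0.01).
#' @param n_iter random-system permutation iterations (default 10000).
#' @param n_perm enrichment gene permutations (default 2000).
#' @param seed master seed (mandatory).
#' @param out_dir optional output directory for artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_config = NULL, de_p = 0.05, fold = 2,
                            cox_p = 0.01, n_iter = 10000, n_perm = 2000,
                            seed, out_dir = NULL) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(de_p > 0, de_p < 1, cox_p > 0, cox_p < 1, fold > 1)
  if (is.null(cohort_config)) cohort_config <- cnamlsig::cohort_config()
  cohort_config$seed <- seed
  structure(list(cohort_config = cohort_config, de_p = de_p, fold = fold,
                 cox_p = cox_p, n_iter = n_iter, n_perm = n_perm,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' End-to-end discovery run
#'
#' Wires the stages together on one cohort: quantile normalization ->
#' per-probe z-transform -> response differential expression (PR vs GR) ->
#' univariate Cox survival filter on the intensively treated -> equal-weight
#' risk score -> median split -> Kaplan-Meier / log-rank -> univariate and
#' adjusted Cox models of the continuous score -> random-gene-set
#' permutation -> mean +/- 1 SD extreme-group differential expression ->
#' running-sum enrichment of the signature genes in the extreme-group
#' ranking. Association analyses use the whole cohort; survival analyses
#' only the intensively treated (with transplant censoring applied).
#' Artifacts are written under `config$out_dir` when set, along with a run
#' manifest; reruns with the same seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-generated cohort (as from
#'   [generate_cohort()]); by default one is generated from
#'   `config$cohort_config`.
#' @return List with `cohort`, `de`, `signature`, `scores`, `km`,
#'   `logrank`, `cox_uni`, `cox_multi`, `permutation`, `extreme_de`,
#'   `enrichment`, `associations`.
#' @export
run_discovery <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort_config)

  expr <- quantile_normalize(cohort$expr)
  zexpr <- z_transform(expr)
  cl <- apply_hsct_censoring(cohort$clinical)
  treated <- cl[cl$treated_intensively, ]

  pr <- cl$sample_id[cl$response == "PR"]
  gr <- cl$sample_id[cl$response == "GR"]
  de <- differential_expression(expr, pr, gr,
                                p_thresh = config$de_p,
                                fold_thresh = config$fold)
  signature <- cox_filter(de, zexpr, treated, p_thresh = config$cox_p)
  if (nrow(signature) == 0)
    stop("discovery stage: no probe survived both filters")

  scores <- split_by_median(compute_risk_score(zexpr, signature))
  scores <- extreme_groups(scores, k_sd = 1)

  st <- merge(treated, scores, by = "sample_id")
  km <- km_estimate(st$os_time, st$os_event, st$median_group)
  lr <- logrank_test(st$os_time, st$os_event, st$median_group)
  cox_uni <- cox_fit(st, "score")
  multi_covs <- intersect(c("score", "age", "eln_favorable", "TET2"),
                          names(st))
  cox_multi <- cox_fit(st, multi_covs)

  perm <- permutation_null(zexpr, treated, signature,
                           n_iter = config$n_iter, seed = config$seed + 1)

  hi <- scores$sample_id[scores$extreme_group == "high_risk"]
  lo <- scores$sample_id[scores$extreme_group == "low_risk"]
  extreme_de <- differential_expression(expr, hi, lo,
                                        p_thresh = config$de_p,
                                        fold_thresh = config$fold)
  ranked <- rank_genes(expr, hi, lo)
  enr <- enrichment_p(ranked, signature$probe_id, n_perm = config$n_perm,
                      seed = config$seed + 2)

  mut_vars <- intersect(c("NPM1", "FLT3_ITD", "ASXL1", "TET2", "DNMT3A",
                          "CEBPA", "eln_favorable"), names(cl))
  assoc <- association_table(cl, scores, binary_vars = mut_vars,
                             continuous_vars = intersect(c("age", "wbc"),
                                                         names(cl)))

  res <- list(cohort = cohort, de = de, signature = signature,
              scores = scores, km = km, logrank = lr, cox_uni = cox_uni,
              cox_multi = cox_multi, permutation = perm,
              extreme_de = extreme_de, enrichment = enr,
              associations = assoc)
  if (!is.null(config$out_dir)) write_discovery_report(res, config)
  res
}

write_discovery_report <- function(res, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_signature_tsv(res$signature, file.path(dir, "signature.tsv"))
  write_scores_csv(res$scores, file.path(dir, "scores.csv"))
  write_km_csv(res$km, file.path(dir, "km_curves.csv"))
  utils::write.csv(as.data.frame(res$cox_multi),
                   file.path(dir, "cox_multivariate.csv"), row.names = FALSE)
  write_null_tsv(res$permutation, file.path(dir, "permutation_null.tsv"))
  utils::write.csv(res$associations, file.path(dir, "associations.csv"),
                   row.names = FALSE)
  manifest <- c(
    sprintf("seed: %s", format(config$seed)),
    sprintf("n_samples: %d", config$cohort_config$n_samples),
    sprintf("n_probes: %d", config$cohort_config$n_probes),
    sprintf("de_p: %g  fold: %g  cox_p: %g", config$de_p, config$fold,
            config$cox_p),
    sprintf("n_iter: %d  n_perm: %d", config$n_iter, config$n_perm),
    sprintf("package: cnamlsig %s",
            as.character(utils::packageVersion("cnamlsig"))))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Score and evaluate an external validation cohort
#'
#' Transfers a discovered signature to an independent probe-level cohort:
#' collapse probes to genes by coefficient of variation, z-standardize
#' within the cohort, match signature members by gene symbol, build the
#' equal-weight score, split at the cohort's own median, and test the split
#' (Kaplan-Meier + log-rank) and the continuous score (univariate Cox).
#' Scores are standardized within each cohort, so they are comparable only
#' within it.
#'
#' @param signature a `cnaml_signature` (gene symbols are used for
#'   matching).
#' @param expr probe-level `expr_mat` with `probe_to_gene` annotation.
#' @param clinical clinical table with `sample_id`, `os_time`, `os_event`.
#' @return List with `scores`, `km`, `logrank`, `cox` (continuous score:
#'   HR, CI, P), `mapped` (the matched signature subset).
#' @export
score_external_cohort <- function(signature, expr, clinical) {
  genes <- collapse_probes_by_cv(expr)
  zg <- z_transform(genes)
  mapped <- map_signature(signature, zg)
  scores <- split_by_median(compute_risk_score(zg, mapped))
  d <- merge(clinical, scores, by = "sample_id")
  km <- km_estimate(d$os_time, d$os_event, d$median_group)
  lr <- logrank_test(d$os_time, d$os_event, d$median_group)
  cox <- cox_fit(d, "score")
  list(scores = scores, km = km, logrank = lr, cox = cox, mapped = mapped)
}
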