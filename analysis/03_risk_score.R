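#!/usr/bin/env Rscript
# Equal-weight z-score risk score from the discovered signature; median
# split for Kaplan-Meier / log-rank, continuous score for Cox models
# (univariate and adjusted for age, ELN group and TET2).

library(cnamlsig)

cohort_dir <- "results/01_cohort"
out <- "results/03_scores"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_annotation_tsv(file.path(cohort_dir, "annotation.tsv"))
expr <- read_expression_tsv(file.path(cohort_dir, "expression.tsv"),
                            probe_to_gene = ann)
clinical <- apply_hsct_censoring(
  read.csv(file.path(cohort_dir, "clinical.csv")))
sig <- read.delim("results/02_signature/signature.tsv")

zexpr <- z_transform(quantile_normalize(expr))
scores <- extreme_groups(split_by_median(compute_risk_score(zexpr, sig)))
write_scores_csv(scores, file.path(out, "scores.csv"))

treated <- merge(clinical[clinical$treated_intensively, ], scores,
                 by = "sample_id")
km <- km_estimate(treated$os_time, treated$os_event, treated$median_group)
write_km_csv(km, file.path(out, "km_curves.csv"))
lr <- logrank_test(treated$os_time, treated$os_event, treated$median_group)

fmt_med <- function(g) {
  m <- km$medians[km$medians$group == g, ]
  if (m$reached) sprintf("%.1f months", m$median) else "not reached"
}
cat(sprintf("median OS: high %s vs low %s; log-rank chisq %.2f, P %.2e\n",
            fmt_med("high"), fmt_med("low"), lr$chisq, lr$p))

uni <- cox_fit(treated, "score")
cat(sprintf("continuous score, univariate: HR %.3f (%.3f-%.3f), P %.2e\n",
            uni$hr, uni$ci_low, uni$ci_high, uni$p))

multi <- cox_fit(treated, c("score", "age", "eln_favorable", "TET2"))
write.csv(as.data.frame(multi), file.path(out, "cox_multivariate.csv"),
          row.names = FALSE)
cat("multivariate model:\n")
print(as.data.frame(multi)[, c("term", "hr", "ci_low", "ci_high", "p")],
      digits = 3)
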