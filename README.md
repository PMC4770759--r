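# cnamlsig

Discovery and validation machinery for small prognostic gene-expression
signatures in cytogenetically normal acute myeloid leukemia (CN-AML), built
as a tested R package plus a sequence of analysis drivers.

CN-AML lacks the chromosomal lesions that anchor risk stratification in the
rest of AML. The workflow implemented here derives a compact mRNA score in
two stages on a discovery cohort — probes separating patients refractory to
induction chemotherapy (PR) from those in continuous remission (GR) by
Student t-test *P* < 0.05 and > 2-fold change, then filtered to probes
whose expression predicts overall survival (univariate Cox Wald
*P* < 0.01, Efron ties, transplant-censored follow-up) — and sums the
per-probe z-values with equal unit weights:

```
score_j = Σ_{g ∈ signature} z_gj ,   z_gj = (x_gj − mean_g) / sd_g
```

The cohort median splits patients into low/high groups for Kaplan–Meier and
log-rank analysis; the continuous score enters uni- and multivariate Cox
models (hazard ratios are per score unit). A 10,000-iteration
random-gene-set permutation test checks that the system beats chance
constructions, and a running-sum (GSEA-style) enrichment analysis with
2,000 gene permutations probes the biology of the score extremes. A seeded
synthetic-cohort generator — one latent prognostic factor driving a planted
co-expressed probe block, exponential survival, induction response, and
mutation covariates — supplies ground truth for all calibration and
recovery experiments; no patient data ship with the package.

## Worked example

The numbered drivers under `analysis/` run the full study on a simulated
160-patient, 5000-probe cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort + planted ground truth
Rscript analysis/02_discover.R      # two-stage signature discovery
Rscript analysis/03_risk_score.R    # score, KM/log-rank, Cox models
Rscript analysis/04_permutation.R   # random-system null
Rscript analysis/05_enrichment.R    # score-extremes DE + enrichment
Rscript analysis/06_associations.R  # clinical/mutation association tables
Rscript analysis/07_validation.R    # transfer to validation cohorts
```

Output from a run at seed 1:

```
differential expression: 11 of 5000 probes selected (PR 26 vs GR 80)
  up-regulated in PR: 11 of 11 selected
survival filter: 9 probes retained (univariate Cox P < 0.01, 106 patients)
planted probes recovered: 9 of 11
median OS: high 15.0 months vs low 38.4 months; log-rank chisq 13.52, P 2.36e-04
continuous score, univariate: HR 1.095 (1.052-1.141), P 1.03e-05
<perm_result> observed Cox P = 1.03e-05; empirical P < 1.00e-04 (10000 iterations, seed 2)
validation cohort (seed 11): 9/9 genes mapped; log-rank P 3.87e-05; score HR 1.138 (1.093-1.186), P 4.67e-10
```

Reading: the response screen finds the planted co-expressed block (all
up-regulated in the refractory group), the survival filter keeps the 9
probes with detectable hazard effects in this cohort, high-scoring patients
die about 2.5× sooner at the median, no random 11-probe system out of
10,000 matches the proposed score's Cox significance, and the signature
transfers to an independent cohort through gene-level collapse and
per-cohort standardization.

Programmatic use mirrors the drivers:

```r
library(cnamlsig)
co  <- generate_cohort(cohort_config(seed = 1))
res <- run_discovery(pipeline_config(seed = 1, n_iter = 1000, n_perm = 500))
res$signature; res$permutation; res$km$medians
```

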