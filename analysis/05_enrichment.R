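#!/usr/bin/env Rscript
# Biology behind the score: differential expression between the mean +/- 1
# SD extreme score groups, then running-sum enrichment of gene sets in the
# resulting ranking with gene-permutation significance. The signature's own
# genes serve as the demonstration set; external GMT collections plug into
# the same call.

library(cnamlsig)

cohort_dir <- "results/01_cohort"
out <- "results/05_enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_annotation_tsv(file.path(cohort_dir, "annotation.tsv"))
expr <- read_expression_tsv(file.path(cohort_dir, "expression.tsv"),
                            probe_to_gene = ann)
sig <- read.delim("results/02_signature/signature.tsv")
scores <- read.csv("results/03_scores/scores.csv")

expr <- quantile_normalize(expr)
hi <- scores$sample_id[scores$extreme_group == "high_risk"]
lo <- scores$sample_id[scores$extreme_group == "low_risk"]
cat(sprintf("extreme groups: %d high-risk vs %d low-risk\n",
            length(hi), length(lo)))

ex_de <- differential_expression(expr, hi, lo)
cat(sprintf("extreme-group DE: %d probes (P < 0.05 and > 2-fold)\n",
            sum(ex_de$selected)))

ranked <- rank_genes(expr, hi, lo)
enr <- enrichment_p(ranked, sig$probe_id, n_perm = 2000, seed = 3L)
write_enrichment_tsv(list(signature = enr),
                     file.path(out, "enrichment.tsv"))
cat(sprintf("signature set: ES %.3f, gene-permutation P %s (leading edge %d genes)\n",
            enr$es,
            if (enr$empirical_p == 0) enr$p_label else format(enr$empirical_p),
            length(enr$leading_edge)))
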