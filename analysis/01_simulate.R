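#!/usr/bin/env Rscript
# Generate the discovery cohort: 160 patients, 5000 probes, an 11-probe
# co-expressed signature whose latent factor drives survival and induction
# response. Writes the expression TSV, probe annotation, clinical CSV and
# the planted ground truth.

library(cnamlsig)

seed <- 1L
out <- "results/01_cohort"
co <- generate_cohort(cohort_config(seed = seed))
write_cohort(co, out)
writeLines(co$truth$signature_probe_ids,
           file.path(out, "planted_probes.txt"))

cl <- co$clinical
cat(sprintf("cohort: %d patients, %d probes (seed %d)\n",
            nrow(cl), nrow(co$expr$values), seed))
cat(sprintf("intensively treated: %d; response GR %d / PR %d\n",
            sum(cl$treated_intensively), sum(cl$response == "GR"),
            sum(cl$response == "PR")))
cat(sprintf("events among treated: %d\n",
            sum(cl$os_event[cl$treated_intensively])))
cat(sprintf("planted probes: %s ...\n",
            paste(head(co$truth$signature_probe_ids, 3), collapse = ", ")))
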