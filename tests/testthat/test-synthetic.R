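test_that("cohort dimensions and clinical schema honour the configuration", {
  co <- generate_cohort(cohort_config(n_samples = 158, n_probes = 5000,
                                      seed = 1))
  expect_identical(dim(co$expr$values), c(5000L, 158L))
  expect_identical(nrow(co$clinical), 158L)
  expect_setequal(
    intersect(c("sample_id", "os_time", "os_event", "dfs_time", "dfs_event",
                "response", "treated_intensively", "hsct_time"),
              names(co$clinical)),
    c("sample_id", "os_time", "os_event", "dfs_time", "dfs_event",
      "response", "treated_intensively", "hsct_time"))
  expect_length(co$truth$signature_probe_ids, 11)
  expect_true(all(co$truth$signature_probe_ids %in% rownames(co$expr$values)))
  # planted probes map to distinct genes
  sig_genes <- co$expr$probe_to_gene[co$truth$signature_probe_ids]
  expect_equal(anyDuplicated(sig_genes), 0L)
  # response classes only among the intensively treated
  expect_true(all(co$clinical$response[!co$clinical$treated_intensively]
                  == "other"))
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  cf <- cohort_config(n_samples = 40, n_probes = 200, seed = 42)
  a <- generate_cohort(cf)
  b <- generate_cohort(cf)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_samples = 40, n_probes = 200,
                                      seed = 43))
  expect_false(identical(a$expr$values, c2$expr$values))
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(n_samples = 0), "dimensions")
  expect_error(cohort_config(n_probes = 20, n_signature = 20), "smaller")
  expect_error(cohort_config(censor_horizon = -1), "positive")
  expect_error(cohort_config(mutation_spec = list(X = c(1.2, 0))), "rates")
})

test_that("event rate is monotone in the censoring horizon", {
  rates <- vapply(c(12, 30, 60, 120), function(h) {
    co <- generate_cohort(cohort_config(n_samples = 400, n_probes = 10,
                                        n_signature = 2, censor_horizon = h,
                                        seed = 5))
    mean(co$clinical$os_event)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("null configuration decouples expression from outcome", {
  co <- generate_cohort(cohort_config(n_samples = 300, n_probes = 2000,
                                      log_hazard_coeff = 0,
                                      response_slope = 0, seed = 11))
  # with the fold gate disabled, the t-test alone selects ~ p_thresh of probes
  pr <- co$clinical$sample_id[co$clinical$response == "PR"]
  gr <- co$clinical$sample_id[co$clinical$response == "GR"]
  de <- differential_expression(co$expr, pr, gr, p_thresh = 0.05,
                                fold_thresh = 1 + 1e-12)
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.02)
  # survival unrelated to the latent factor
  cl <- co$clinical[co$clinical$treated_intensively, ]
  cl$latent <- co$truth$latent_factor[cl$sample_id]
  fit <- cox_fit(cl, "latent")
  expect_lt(abs(fit$coef), 0.35)
})

test_that("Cox regression on the true latent factor recovers the planted
           log-hazard coefficient", {
  co <- generate_cohort(cohort_config(seed = 9))
  cl <- co$clinical[co$clinical$treated_intensively, ]
  cl$latent <- co$truth$latent_factor[cl$sample_id]
  fit <- cox_fit(cl, "latent")
  expect_gt(fit$ci_low, 1)              # CI excludes no-effect
  expect_true(log(fit$ci_low) < 0.7 && 0.7 < log(fit$ci_high))
})

test_that("written cohorts round-trip through the preprocessing readers", {
  co <- generate_cohort(cohort_config(n_samples = 12, n_probes = 30,
                                      n_signature = 3, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  ann <- read_annotation_tsv(paths["annotation"])
  back <- read_expression_tsv(paths["expression"], probe_to_gene = ann)
  expect_equal(back$values, co$expr$values, tolerance = 1e-12)
  expect_identical(back$probe_to_gene, co$expr$probe_to_gene)
  clin <- read.csv(paths["clinical"])
  expect_identical(nrow(clin), 12L)
})
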