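test_that("transplant censoring rewrites time and status only where a
           transplant occurred", {
  cl <- data.frame(sample_id = c("a", "b", "c"),
                   os_time = c(20, 15, 8), os_event = c(1L, 1L, 0L),
                   hsct_time = c(6, NA, NA))
  out <- apply_hsct_censoring(cl)
  expect_equal(out$os_time, c(6, 15, 8))
  expect_equal(out$os_event, c(0L, 1L, 0L))
  # event accounting: before - events among transplanted
  expect_identical(sum(out$os_event), sum(cl$os_event) - 1L)

  no_tx <- cl; no_tx$hsct_time <- NA_real_
  expect_identical(apply_hsct_censoring(no_tx), no_tx)

  bad <- cl; bad$hsct_time[1] <- 25
  expect_error(apply_hsct_censoring(bad), "exceeds os_time.*a")
})

test_that("Kaplan-Meier estimate matches the hand-computed product limit", {
  # no events: flat curve, median not reached
  km0 <- km_estimate(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(km0$curves$surv == 1))
  expect_false(km0$medians$reached)
  expect_true(is.na(km0$medians$median))

  # all events at 1, 2, 3: S = 2/3, 1/3, 0; median 2
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$curves$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km1$medians$median, 2)

  # censoring-only tail leaves the curve flat
  km2 <- km_estimate(c(1, 2, 4, 6), c(1, 1, 0, 0))
  tail_surv <- km2$curves$surv[km2$curves$time >= 2]
  expect_true(all(tail_surv == 0.5))

  # monotone non-increasing, S(0) = 1 implied by first step <= 1
  set.seed(30)
  kmr <- km_estimate(rexp(50, 0.1), rbinom(50, 1, 0.7))
  expect_true(all(diff(kmr$curves$surv) <= 1e-12))
  expect_lte(max(kmr$curves$surv), 1)
})

test_that("log-rank reproduces the hand-computed O-E/V statistic", {
  # Six subjects, group A: (1,event) (3,event) (5,censored),
  # group B: (2,event) (4,censored) (6,event).
  # Risk-set walk gives O_A = 2, E_A = 0.5 + 0.4 + 0.5 = 1.4,
  # V = 0.25 + 0.24 + 0.25 = 0.74, chi-square = 0.36 / 0.74.
  t <- c(1, 3, 5, 2, 4, 6); e <- c(1, 1, 0, 1, 0, 1)
  g <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chisq, (2 - 1.4)^2 / 0.74, tolerance = 1e-9)
  expect_equal(lr$p, pchisq((2 - 1.4)^2 / 0.74, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  # label swap leaves the statistic unchanged
  swap <- logrank_test(t, e, rep(c("B", "A"), each = 3))
  expect_equal(swap$chisq, lr$chisq, tolerance = 1e-12)

  # identical groups: statistic 0, P 1
  same <- logrank_test(rep(c(1, 2, 3), 2), rep(c(1, 1, 0), 2),
                       rep(c("A", "B"), each = 3))
  expect_lt(same$chisq, 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-9)

  expect_error(logrank_test(1:4, rep(0, 4), rep(c("A", "B"), 2)),
               "zero events")
  expect_error(logrank_test(1:4, rep(1, 4), rep("A", 4)), ">= 2 groups")
})

test_that("Cox fit agrees with grid-search maximization of the Efron
           partial likelihood", {
  # 8 subjects with tied event times to exercise the Efron correction
  time <- c(2, 2, 3, 5, 5, 5, 8, 9)
  status <- c(1, 1, 1, 1, 1, 0, 1, 0)
  x <- c(1, 0, 1, 1, 0, 1, 0, 0)
  cl <- data.frame(os_time = time, os_event = status, grp = x)
  fit <- cox_fit(cl, "grp")
  oracle <- grid_cox_coef(time, status, x)
  expect_equal(fit$coef, oracle, tolerance = 1e-4)

  # a second, untied configuration
  time2 <- c(1, 2, 3, 4, 6, 7, 9, 12)
  status2 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x2 <- c(0, 1, 1, 0, 1, 0, 0, 1)
  cl2 <- data.frame(os_time = time2, os_event = status2, grp = x2)
  expect_equal(cox_fit(cl2, "grp")$coef,
               grid_cox_coef(time2, status2, x2), tolerance = 1e-4)
})

test_that("Cox reporting conventions hold and errors are explicit", {
  co <- generate_cohort(cohort_config(n_samples = 120, n_probes = 10,
                                      n_signature = 2, seed = 31))
  cl <- co$clinical
  cl$latent <- co$truth$latent_factor[cl$sample_id]
  fit <- cox_fit(cl, c("latent", "age"))
  expect_identical(nrow(fit), 2L)
  expect_equal(fit$hr, exp(fit$coef), tolerance = 1e-12)
  expect_equal(fit$ci_low, exp(fit$coef - 1.96 * fit$se), tolerance = 1e-12)
  expect_true(is.numeric(attr(fit, "loglik")))

  cl_na <- cl; cl_na$age[3] <- NA
  expect_error(cox_fit(cl_na, c("latent", "age")), "missing covariate")
  few <- data.frame(os_time = 1:4, os_event = c(1, 0, 0, 0), x = rnorm(4))
  expect_error(cox_fit(few, "x"), "fewer than 2 events")
  sep <- data.frame(os_time = c(1, 2, 3, 10, 11, 12),
                    os_event = c(1, 1, 1, 1, 1, 1),
                    x = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_fit(sep, "x"), "separation|converge")
})

test_that("Wald chi-square from a binary Cox covariate approaches the
           log-rank statistic on large cohorts", {
  set.seed(32)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, 0.05 * exp(0.3 * x))
  cens <- runif(n, 0, 30)
  cl <- data.frame(os_time = pmin(t0, cens),
                   os_event = as.integer(t0 <= cens), x = x)
  fit <- cox_fit(cl, "x")
  lr <- logrank_test(cl$os_time, cl$os_event, cl$x)
  expect_lt(abs(fit$z^2 - lr$chisq) / lr$chisq, 0.05)
})
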