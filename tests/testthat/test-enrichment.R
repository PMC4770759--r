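test_that("gene ranking is the signed t statistic, descending", {
  set.seed(50)
  v <- matrix(rnorm(30 * 12, 8), 30, 12)
  v[1:3, 1:6] <- v[1:3, 1:6] + 2      # up in group A
  v[4:5, 1:6] <- v[4:5, 1:6] - 2      # down in group A
  m <- make_expr(v)
  a <- sprintf("s%02d", 1:6); b <- sprintf("s%02d", 7:12)
  rk <- rank_genes(m, a, b)
  expect_true(all(diff(rk$metric) <= 0))
  expect_true(all(sprintf("p%02d", 1:3) %in% head(rk$id, 5)))
  expect_true(all(sprintf("p%02d", 4:5) %in% tail(rk$id, 5)))

  # per-gene metric equals the t.test statistic
  ora <- t.test(v[1, 1:6], v[1, 7:12], var.equal = TRUE)$statistic
  expect_equal(rk$metric[rk$id == "p01"], unname(ora), tolerance = 1e-12)

  # antisymmetry under group swap
  rv <- rank_genes(m, b, a)
  expect_equal(rv$metric[match(rk$id, rv$id)], -rk$metric, tolerance = 1e-12)

  # an equal-mean gene sits near the middle with metric ~ 0
  flat <- make_expr(rbind(v, c(rep(8, 12))))
  rkf <- rank_genes(flat, a, b)
  expect_lt(abs(rkf$metric[rkf$id == "p31"]), 2)
})

test_that("running sum matches the hand-walked toy and the classic KS
           reduction", {
  # 10 genes, set at every other rank, constant metric, p = 0:
  # hits +1/5, misses -1/5 -> walk .2 0 .2 0 ... ; ES = 0.2
  ranked <- data.frame(id = paste0("g", 1:10), metric = rep(1, 10))
  set_alt <- paste0("g", c(1, 3, 5, 7, 9))
  r <- enrichment_score(ranked, set_alt, p = 0)
  expect_equal(r$es, 0.2, tolerance = 1e-12)
  expect_equal(r$running_sum,
               cumsum(rep(c(0.2, -0.2), 5)), tolerance = 1e-12)
  # conservation: the walk returns to zero
  expect_lt(abs(r$running_sum[10]), 1e-12)

  # top-k set: walk peaks at exactly 1
  top <- enrichment_score(ranked, paste0("g", 1:4), p = 0)
  expect_equal(top$es, 1, tolerance = 1e-12)
  expect_setequal(top$leading_edge, paste0("g", 1:4))

  # p = 0 equals the brute-force KS statistic on a random fixture
  set.seed(51)
  rk <- data.frame(id = paste0("x", 1:40),
                   metric = sort(rnorm(40), decreasing = TRUE))
  gs <- sample(rk$id, 9)
  expect_equal(enrichment_score(rk, gs, p = 0)$es,
               ks_enrichment(rk$id, gs), tolerance = 1e-12)
})

test_that("weighted running sum agrees with an independent GSEA
           implementation", {
  set.seed(52)
  m <- sort(rnorm(60, sd = 2), decreasing = TRUE)
  names(m) <- paste0("g", 1:60)
  gs <- sample(names(m), 12)
  idx <- which(names(m) %in% gs)
  for (p in c(0, 1)) {
    expect_equal(enrichment_score(m, gs, p = p)$es,
                 fgsea::calcGseaStat(m, selectedStats = idx, gseaParam = p),
                 tolerance = 1e-9)
  }
})

test_that("ES is invariant to metric rescaling at p = 0 and flips sign
           under ranking reversal", {
  set.seed(53)
  rk <- data.frame(id = paste0("x", 1:30),
                   metric = sort(rexp(30), decreasing = TRUE))
  gs <- sample(rk$id, 6)
  es <- enrichment_score(rk, gs, p = 0)$es
  scaled <- rk; scaled$metric <- rk$metric * 1000
  expect_equal(enrichment_score(scaled, gs, p = 0)$es, es, tolerance = 1e-12)
  rev_rk <- rk[rev(seq_len(nrow(rk))), ]
  expect_equal(enrichment_score(rev_rk, gs, p = 0)$es, -es, tolerance = 1e-12)
})

test_that("gene-permutation P counts extreme null scores, with a bound
           label when none reach the observed", {
  ranked <- data.frame(id = paste0("g", 1:12),
                       metric = seq(6, -5, length.out = 12))
  gs <- paste0("g", 1:3)
  r <- enrichment_p(ranked, gs, n_perm = 4, seed = 5)
  manual <- mean(r$null_es >= r$es)
  expect_equal(r$empirical_p, manual)
  if (r$empirical_p == 0) expect_match(r$p_label, "< 0.25")

  # determinism
  r2 <- enrichment_p(ranked, gs, n_perm = 4, seed = 5)
  expect_identical(r$null_es, r2$null_es)

  # two-sided option uses |ES|
  r3 <- enrichment_p(ranked, gs, n_perm = 50, seed = 6,
                     alternative = "two.sided")
  expect_equal(r3$empirical_p, mean(abs(r3$null_es) >= abs(r3$es)))
})

test_that("a random gene set under a null ranking is unremarkable", {
  # the two-sided P is calibrated for null sets; the default one-sided P
  # conditions on the observed ES sign and is stochastically smaller
  set.seed(54)
  ps <- vapply(1:40, function(i) {
    rk <- data.frame(id = paste0("g", 1:50),
                     metric = sort(rnorm(50), decreasing = TRUE))
    set.seed(1000 + i)
    gs <- sample(rk$id, 8)
    enrichment_p(rk, gs, n_perm = 100, seed = i,
                 alternative = "two.sided")$empirical_p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(min(ps), 0.001)
})

test_that("GMT round-trip works on a small written file", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g4", "g5"))
})
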