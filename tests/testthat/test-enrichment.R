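test_that("Fisher p equals hypergeometric enumeration and handles
           degenerate tables", {
  f <- fisher_exact_2x2(5, 5, 5, 5)
  expect_identical(f$odds_ratio, 1)
  expect_identical(f$p_value, 1)

  f <- fisher_exact_2x2(3, 1, 1, 3)
  expect_equal(f$p_value, enum_fisher_p(3, 1, 1, 3), tolerance = 1e-12)
  expect_identical(f$odds_ratio, 9)

  # empty margin
  f <- fisher_exact_2x2(0, 0, 3, 4)
  expect_true(is.na(f$odds_ratio))
  expect_identical(f$p_value, 1)
  # infinite odds
  expect_identical(fisher_exact_2x2(4, 0, 1, 5)$odds_ratio, Inf)

  set.seed(17)
  for (i in 1:300) {
    t <- as.vector(rmultinom(1, sample(4:40, 1), runif(4) + 0.05))
    f <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_equal(f$p_value, enum_fisher_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    # independent reference implementation
    expect_equal(f$p_value,
                 fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the protection table counts classes correctly and detects the
           planted association", {
  cfg <- synthetic_config(seed = 5)
  g <- generate_genome(cfg)
  m <- generate_methylation(cfg, g$probes, g$protected_probe_ids)
  cls <- classify_cpgs(m$beta, classifier_params(), g$probes)
  w <- build_windows(g$probes, setNames(nchar(g$genome), names(g$genome)))
  # protected set planted to be exactly the triplex-positive set
  w$triplex_positive <- w$probe_id %in% g$protected_probe_ids
  pt <- hm_protection_table(cls, w)
  expect_identical(sum(pt$table) + pt$n_other, nrow(w))
  expect_identical(sum(pt$table["HM", ]),
                   sum(cls$klass == "HM"))
  expect_lt(pt$fisher$odds_ratio, 1)
  expect_lt(pt$fisher$p_value, 0.001)
})

test_that("without a planted association the protection p-value is
           calibrated", {
  set.seed(18)
  n_rep <- 500L
  n <- 600L
  ps <- vapply(seq_len(n_rep), function(r) {
    klass <- sample(c("HM", "NHM"), n, TRUE, prob = c(0.35, 0.65))
    pos <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.4, 0.6))
    fisher_exact_2x2(sum(klass == "HM" & pos), sum(klass == "HM" & !pos),
                     sum(klass == "NHM" & pos),
                     sum(klass == "NHM" & !pos))$p_value
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * se)
})

test_that("independence-planted synthetic cohorts keep the protection test
           calibrated", {
  cfg0 <- synthetic_config(n_probes = 300L, link_protection = FALSE,
                           seed = 1)
  g <- generate_genome(cfg0)
  cl <- setNames(nchar(g$genome), names(g$genome))
  w <- build_windows(g$probes, cl)
  w$triplex_positive <- w$probe_id %in% g$protected_probe_ids
  n_rep <- 60L
  ps <- vapply(seq_len(n_rep), function(s) {
    cfg <- synthetic_config(n_probes = 300L, link_protection = FALSE,
                            seed = 4000L + s)
    m <- generate_methylation(cfg, g$probes, g$protected_probe_ids)
    cls <- classify_cpgs(m$beta, classifier_params(), g$probes)
    hm_protection_table(cls, w)$fisher$p_value
  }, numeric(1))
  # an exact conditional test has discrete, conservative p-values: the
  # calibration property is that rejection never exceeds the nominal level
  for (alpha in c(0.01, 0.05, 0.1, 0.2)) {
    expect_lte(mean(ps < alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / n_rep))
  }
  # and p-values do spread over the unit interval rather than piling up
  expect_gt(mean(ps > 0.5), 0.25)
})

test_that("TFO clustering matches a brute-force union merge", {
  p <- enrichment_params()
  h1 <- data.frame(rna_start = 10L, rna_end = 22L, window_id = "w1")
  d <- cluster_dbds(h1, p)
  expect_identical(d$rna_start, 10L)
  expect_identical(d$rna_end, 22L)
  expect_identical(d$n_tfos, 1L)

  h2 <- data.frame(rna_start = c(10L, 21L), rna_end = c(22L, 35L),
                   window_id = c("w1", "w2"))
  d <- cluster_dbds(h2, p)
  expect_identical(nrow(d), 1L)
  expect_identical(d$rna_end, 35L)
  expect_identical(d$n_target_regions_hit, 2L)

  expect_identical(nrow(cluster_dbds(empty <- data.frame(
    rna_start = integer(0), rna_end = integer(0),
    window_id = character(0)), p)), 0L)

  set.seed(19)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    gap <- sample(0:5, 1)
    s <- sample.int(200L, n, replace = TRUE)
    h <- data.frame(rna_start = s, rna_end = s + sample.int(15L, n, TRUE),
                    window_id = sprintf("w%d", sample.int(8L, n, TRUE)))
    d <- cluster_dbds(h, enrichment_params(gap_tolerance = gap))
    oracle <- brute_merge_intervals(h$rna_start, h$rna_end, gap)
    expect_equal(unname(as.matrix(d[, c("rna_start", "rna_end")])),
                 unname(oracle))
    expect_identical(sum(d$n_tfos), n)
  }
})

test_that("domain enrichment is seeded, one-sided, and flags planted
           domains", {
  # planted: the domain hits many targets but few background regions
  set.seed(20)
  target_hits <- data.frame(
    rna_start = rep(100L, 25L), rna_end = rep(115L, 25L),
    window_id = sprintf("t%02d", 1:25))
  bg_ids <- sprintf("b%03d", 1:200)
  bg_hits <- data.frame(rna_start = rep(100L, 5L),
                        rna_end = rep(115L, 5L),
                        window_id = bg_ids[1:5])
  dbds <- cluster_dbds(target_hits, enrichment_params())
  enr <- dbd_enrichment(dbds, target_hits, bg_hits, bg_ids, 25L,
                        enrichment_params(seed = 42))
  expect_identical(enr$n_target_regions_hit, 25L)
  expect_lte(enr$empirical_p, 0.05)
  expect_gt(enr$z_score, 2)
  # determinism under the seed
  enr2 <- dbd_enrichment(dbds, target_hits, bg_hits, bg_ids, 25L,
                         enrichment_params(seed = 42))
  expect_identical(enr, enr2)
  # a domain hitting zero targets cannot look enriched
  dbd0 <- data.frame(rna_start = 500L, rna_end = 520L, n_tfos = 1L,
                     n_target_regions_hit = 0L)
  enr0 <- dbd_enrichment(dbd0, target_hits[0, ], bg_hits, bg_ids, 25L,
                         enrichment_params(seed = 1))
  expect_gte(enr0$empirical_p, 0.5)
  # background smaller than the draw size is an error
  expect_error(dbd_enrichment(dbds, target_hits, bg_hits, bg_ids[1:10],
                              25L, enrichment_params()), "background")
})

test_that("rank-sum test matches enumeration exactly and wilcox.test
           approximately", {
  r <- rank_sum_test(c(3, 1, 2), c(3, 1, 2))
  expect_identical(r$p_value, 1)
  r <- rank_sum_test(rep(5, 4), rep(5, 3))
  expect_identical(r$p_value, 1)

  # x=[1,2], y=[3,4]: 6 assignments, U in {0,1,2,2,3,4} -> two-sided 1/3
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_identical(r$U, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  set.seed(22)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1), 0.5)
    a <- rank_sum_test(x, y)
    expect_identical(a$method, "exact")
    b <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(a$p_value, b$p.value, tolerance = 1e-12)
  }
  # normal approximation vs exact enumeration on continuous 10+10 fuzz
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.4)
    approx <- rank_sum_test(x, y, exact = FALSE)$p_value
    exact <- rank_sum_test(x, y, exact = TRUE)$p_value
    expect_lt(abs(approx - exact), 0.01)
  }
  # with ties the approximation matches the reference implementation
  for (i in 1:10) {
    x <- sample(1:5, 12, TRUE); y <- sample(1:5, 15, TRUE)
    a <- rank_sum_test(x, y, exact = FALSE)$p_value
    b <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                      correct = TRUE)$p.value)
    expect_equal(a, b, tolerance = 1e-9)
  }
})
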