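test_that("cluster enumeration builds every one- and two-residue cluster", {
  peps <- derivative_panel_sequences()
  cl <- enumerate_clusters(peps)
  expect_length(cl, 30)               # 2 positions x (C(5,1) + C(5,2))
  w1 <- Filter(function(c) c$position == 1 &&
                 identical(c$residues, "W"), cl)[[1]]
  expect_setequal(w1$members, peps[grepl("K\\(ac\\)W", peps)])
  expect_length(w1$members, 4)
  expect_length(w1$nonmembers, 12)
  expect_true(all(vapply(cl, function(c)
    length(intersect(c$members, c$nonmembers)) == 0, TRUE)))
  # an alphabet letter absent from the panel gives an untestable cluster
  y1 <- Filter(function(c) c$position == 1 &&
                 identical(c$residues, "Y"), cl)[[1]]
  expect_false(y1$testable)
  # a single residue covering every peptide is untestable (no nonmembers)
  cl2 <- enumerate_clusters(c("AK(ac)A", "CK(ac)A"), alphabet = "A",
                            positions = 1)
  expect_false(cl2[[1]]$testable)
})

test_that("cluster t-test matches the pooled-variance oracle", {
  cl <- structure(list(position = 1L, residues = "W",
                       members = c("p1", "p2", "p3"),
                       nonmembers = c("p4", "p5", "p6"),
                       testable = TRUE, id = "+1:W"),
                  class = "kdac_cluster")
  f <- c(p1 = 10, p2 = 12, p3 = 11, p4 = 10.5, p5 = 11.5, p6 = 11)
  res <- cluster_interaction_ttest(cl, f)
  ref <- t.test(f[1:3], f[4:6], var.equal = TRUE)
  expect_equal(res$t_statistic, unname(ref$statistic))
  expect_equal(res$p_raw, ref$p.value)
  expect_gt(res$p_raw, 0.5)           # clearly not significant

  # identical groups: t = 0, p = 1
  res0 <- cluster_interaction_ttest(cl, c(p1 = 5, p2 = 6, p3 = 7,
                                          p4 = 5, p5 = 6, p6 = 7))
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_raw, 1)

  # relabelling members/nonmembers flips the sign only
  cl_sw <- cl; cl_sw$members <- cl$nonmembers; cl_sw$nonmembers <- cl$members
  r1 <- cluster_interaction_ttest(cl, f)
  r2 <- cluster_interaction_ttest(cl_sw, f)
  expect_equal(r1$t_statistic, -r2$t_statistic)
  expect_equal(r1$p_raw, r2$p_raw)

  # missing peptides count as zero frequency
  res_m <- cluster_interaction_ttest(cl, c(p1 = 40, p2 = 41, p3 = 39))
  ref_m <- t.test(c(40, 41, 39), c(0, 0, 0), var.equal = TRUE)
  expect_equal(res_m$p_raw, ref_m$p.value)
})

test_that("Mann-Whitney activity test: exact small-sample behaviour", {
  cl <- structure(list(position = 1L, residues = "W",
                       members = c("a", "b", "c"),
                       nonmembers = c("d", "e", "f"),
                       testable = TRUE, id = "+1:W"),
                  class = "kdac_cluster")
  act <- c(a = 5, b = 6, c = 7, d = 1, e = 2, f = 3)
  res <- cluster_activity_mwu(cl, act)
  expect_equal(res$U_statistic, 9)     # all member wins
  expect_equal(res$p_value, 0.1)       # 2/20 arrangements, two-sided
  expect_true(res$exact)
  expect_equal(res$direction, "enhanced")
  res_inv <- cluster_activity_mwu(cl, c(a = 1, b = 2, c = 3,
                                        d = 5, e = 6, f = 7))
  expect_equal(res_inv$direction, "inhibited")
  expect_equal(res_inv$p_value, 0.1)
})

test_that("exact Mann-Whitney equals permutation enumeration for n <= 8", {
  set.seed(21)
  for (n1 in c(2, 3, 5, 8)) for (n2 in c(2, 4, 8)) {
    for (rep in 1:3) {
      x <- runif(n1); y <- runif(n2)
      ours <- mwu_test(x, y)
      expect_true(ours$exact)
      expect_equal(ours$p_value, oracle_mwu_exact(x, y))
      expect_equal(ours$p_value, wilcox.test(x, y, exact = TRUE)$p.value)
    }
  }
  # tie-corrected normal approximation tracks wilcox.test
  x <- c(1, 2, 2, 3, 5, 6, 7, 7, 8); y <- c(2, 3, 3, 4, 6, 9, 9, 10, 11)
  ours <- mwu_test(x, y)
  expect_false(ours$exact)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("two-sided Fisher test matches enumeration and stays finite at extremes", {
  # [[10,0],[0,10]]: p = 2 / C(20,10)
  res <- fisher_exact_2x2(10, 0, 0, 10)
  expect_equal(res$p_value, 2 / choose(20, 10))
  # random tables with margins <= 30 against enumeration and fisher.test
  set.seed(17)
  for (i in 1:60) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    ours <- fisher_exact_2x2(a, b, c_, d)
    expect_equal(ours$p_value, oracle_fisher_2x2(a, b, c_, d),
                 tolerance = 1e-12)
    expect_equal(ours$p_value,
                 fisher.test(matrix(c(a, c_, b, d), 2))$p.value,
                 tolerance = 1e-9)
  }
  # identical masks, 100 frames half true: overwhelming association
  m <- rep(c(TRUE, FALSE), each = 50)
  res2 <- cooccurrence_fisher(m, m)
  expect_lt(res2$p_value, 1e-20)
  expect_equal(res2$odds_direction, "positive")
  # log-space survives counts that underflow naive products
  big <- cooccurrence_fisher(rep(c(TRUE, FALSE), each = 6250),
                             rep(c(TRUE, FALSE), each = 6250))
  expect_true(is.finite(big$log10_p))
  expect_lt(big$log10_p, -1000)
  # degenerate margin: warning and p = 1
  expect_warning(res3 <- cooccurrence_fisher(rep(TRUE, 10),
                                             rep(c(TRUE, FALSE), 5)),
                 "degenerate")
  expect_equal(res3$p_value, 1)
})

test_that("Fisher null distribution is approximately uniform", {
  set.seed(31)
  n <- 400
  ps <- replicate(n, {
    a <- runif(60) < 0.5; b <- runif(60) < 0.5
    cooccurrence_fisher(a, b)$p_value
  })
  # discrete test, so compare conservatively: no excess of small p
  expect_lt(mean(ps <= 0.05), 0.08)
  expect_gt(mean(ps), 0.4)
})

test_that("Pearson correlation reproduces closed-form and sign behaviour", {
  x <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  y <- 2 * x + 1
  res <- activity_interaction_correlation(x, y)
  expect_equal(res$r, 1)
  expect_equal(res$r_squared, 1)
  expect_lt(res$p_value, 0.01)
  expect_equal(unname(res$slope), 2)
  expect_equal(unname(res$intercept), 1)
  # exclusion is honoured
  x2 <- c(x, f = 100); y2 <- c(y, f = -50)
  res2 <- activity_interaction_correlation(x2, y2, exclude = "f")
  expect_equal(res2$r, 1)
  expect_equal(res2$n, 5)
  # anticorrelation gives negative r
  expect_lt(activity_interaction_correlation(x, -y)$r, 0)
  expect_error(activity_interaction_correlation(x[1:2], y[1:2]), ">= 3")
  expect_error(activity_interaction_correlation(x, c(a = 1, b = 1, c = 1,
                                                     d = 1, e = 1)),
               "zero variance")
})

test_that("two-stage analysis flags a planted cluster and controls direction", {
  peps <- derivative_panel_sequences()
  # frequencies: W-at-+1 peptides interact with residue 500 at ~40%,
  # everyone else ~2%
  set.seed(8)
  tabs <- setNames(lapply(peps, function(s) {
    w <- residue_at(parse_peptide(s), 1) == "W"
    pct <- max(1, rnorm(1, if (w) 40 else 2, 1))
    make_freqtable(data.frame(resname = "HIS", resno = 500L, position = 1L,
                              itype = "contact", percent_raw = pct,
                              percent = as.integer(trunc(pct))), s)
  }), peps)
  act <- setNames(ifelse(grepl("K\\(ac\\)W", peps), 5, 1) *
                    exp(rnorm(length(peps), 0, 0.05)), peps)
  res <- run_selectivity_analysis(tabs, act)
  w_row <- res$interaction_tests[res$interaction_tests$cluster == "+1:W", ]
  expect_true(w_row$significant)
  expect_true(w_row$selectivity_associated)
  w_act <- res$activity_tests[res$activity_tests$cluster == "+1:W", ]
  expect_true(w_act$significant)
  expect_equal(w_act$direction, "enhanced")
  # Bonferroni adjustment uses the family size
  expect_equal(res$interaction_tests$p_adjusted,
               pmin(1, res$family_size * res$interaction_tests$p_raw))
})
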