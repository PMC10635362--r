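test_that("unified pseudotime maps branches around the shared root", {
  expect_equal(unify_pseudotime("T", 0.7), 0.7)
  expect_equal(unify_pseudotime("myeloid", 0), 0)
  expect_equal(unify_pseudotime("myeloid", 0.5), -0.5)
  expect_error(unify_pseudotime("T", 1.2), "\\[0, 1\\]")
  expect_error(unify_pseudotime("B", 0.5), "Unknown branch")
})

test_that("spectrum bins partition [-1, 1] with the stated conventions", {
  s <- bin_spectrum(rep(0.99, 10))
  expect_equal(s$proportion[20], 1)
  expect_equal(sum(s$proportion), 1)

  s2 <- bin_spectrum(c(-0.95, -0.05, 0.05, 0.95))
  expect_equal(which(s2$proportion > 0), c(1, 10, 11, 20))
  expect_equal(s2$proportion[c(1, 10, 11, 20)], rep(0.25, 4))

  # value exactly 1 falls in the final (closed) bin; edges are left-closed
  expect_equal(bin_spectrum(1)$proportion[20], 1)
  expect_equal(which(bin_spectrum(0.1)$proportion > 0), 12)
  expect_equal(which(bin_spectrum(-1)$proportion > 0), 1)

  empty <- bin_spectrum(numeric(0))
  expect_equal(empty$n_cells, rep(0, 20))
  expect_equal(empty$proportion, rep(0, 20))
  expect_equal(nrow(empty), 20)
  expect_error(bin_spectrum(1.5), "\\[-1, 1\\]")
})

test_that("spectrum proportions sum to one for random inputs", {
  for (i in 1:20) {
    set.seed(i)
    x <- runif(sample(1:200, 1), -1, 1)
    expect_lt(abs(sum(bin_spectrum(x)$proportion) - 1), 1e-9)
  }
})

test_that("KS statistic and p-value follow the two-sample contract", {
  same <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)

  disjoint <- ks_compare(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(disjoint$statistic, 1)

  expect_equal(ks_compare(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)
  expect_error(ks_compare(numeric(0), 1), "non-empty")
})

test_that("KS D matches the brute-force ECDF oracle and stats::ks.test", {
  for (i in 1:50) {
    set.seed(i)
    a <- sample(1:15, sample(2:30, 1), replace = TRUE) / 4
    b <- sample(1:15, sample(2:30, 1), replace = TRUE) / 4
    got <- ks_compare(a, b)
    expect_identical(got$statistic, brute_ks_d(a, b))
  }
  # asymptotic p cross-check on tie-free data
  set.seed(99)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  ref <- stats::ks.test(a, b, exact = FALSE)
  got <- ks_compare(a, b)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("rank-sum exact enumeration matches the worked cases", {
  r1 <- rank_sum_compare(c(1, 2), c(3, 4))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1 / 3)

  r2 <- rank_sum_compare(c(1, 2, 2), c(1, 2, 2))
  expect_equal(r2$p_value, 1)

  r3 <- rank_sum_compare(1, 2)
  expect_equal(r3$p_value, 1)

  tied <- rank_sum_compare(c(2, 2), c(2, 2, 2))
  expect_true(tied$degenerate)
  expect_equal(tied$p_value, 1)
})

test_that("rank-sum p agrees with independent oracles", {
  # tie-free: stats::wilcox.test exact
  for (i in 1:25) {
    set.seed(i)
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
    got <- rank_sum_compare(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
  }
  # with ties: independent rank-sum enumeration
  for (i in 1:25) {
    set.seed(100 + i)
    a <- sample(1:4, sample(2:6, 1), replace = TRUE)
    b <- sample(1:4, sample(2:6, 1), replace = TRUE)
    expect_equal(rank_sum_compare(a, b)$p_value, brute_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
  # large-sample branch: normal approximation stays close to wilcox.test
  set.seed(7)
  a <- rnorm(40); b <- rnorm(45, 0.3)
  got <- rank_sum_compare(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("BMP-like classification uses the strict 30% boundary", {
  expect_equal(as.character(classify_bmp(0)), "Low")
  expect_equal(as.character(classify_bmp(150 / 400)), "High")
  expect_equal(as.character(classify_bmp(0.30)), "Low")
  expect_equal(attr(classify_bmp(0.1), "boundary_rule"),
               "strict_gt_threshold_else_Low")
  expect_error(classify_bmp(1.2), "\\[0, 1\\]")
})

test_that("state proportions partition blasts and recover planted classes", {
  proj <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 400),
    predicted_label = c(rep("ETP", 150), rep("DP", 250),     # 37.5% BMP-like
                        rep("HSPC", 60), rep("ProT", 340)))  # 15% BMP-like
  sp <- state_proportions(proj)
  sp <- sp[order(sp$sample_id), ]
  expect_equal(sp$bmp_fraction, c(0.375, 0.15))
  expect_equal(as.character(sp$bmp_class), c("High", "Low"))
  expect_true(all(abs(sp$bmp_like + sp$pro_t + sp$pre_t +
                        sp$post_commit + sp$myeloid_other - 1) < 1e-9))
})
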