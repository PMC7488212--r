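test_that("rank-sum null: trivial case, mass, symmetry, subset count", {
  n <- rank_sum_null(1, 1)
  expect_equal(n$w, c(1, 2))
  expect_equal(n$prob, c(0.5, 0.5))
  for (sz in list(c(3, 4), c(8, 6), c(5, 5))) {
    d <- rank_sum_null(sz[1], sz[2])
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    mu <- sz[1] * (sz[1] + sz[2] + 1) / 2
    expect_equal(d$prob, rev(d$prob))            # symmetric about the mean
    expect_equal(mean(range(d$w)), mu)
  }
  # (8, 6): 3003 equally likely subsets
  d86 <- rank_sum_null(8, 6)
  expect_equal(sum(d86$prob * choose(14, 8)), choose(14, 8), tolerance = 1e-9)
  expect_true(all(abs(d86$prob * 3003 - round(d86$prob * 3003)) < 1e-9))
  expect_error(rank_sum_null(16, 3), "1..15")
})

test_that("rank-sum DP equals enumeration for all sizes up to 6", {
  for (n1 in 1:6) for (n2 in 1:6) {
    got <- rank_sum_null(n1, n2)
    oracle <- rank_sum_enum_oracle(n1, n2)
    expect_equal(got$w, oracle$w)
    expect_equal(got$prob, oracle$prob, tolerance = 1e-12)
  }
})

test_that("signed-rank DP equals enumeration up to n = 12", {
  for (n in c(1:8, 10, 12)) {
    got <- signed_rank_null(n)
    oracle <- signed_rank_enum_oracle(n)
    expect_equal(got$w, oracle$w)
    expect_equal(got$prob, oracle$prob, tolerance = 1e-12)
  }
})

test_that("rank-sum test p-values match enumeration-derived constants", {
  expect_equal(rank_sum_test(W = 60, n1 = 8, n2 = 6)$p_raw, 1)
  expect_equal(rank_sum_test(W = 80, n1 = 8, n2 = 6)$p_raw, 24 / 3003,
               tolerance = 1e-12)
  expect_equal(rank_sum_test(W = 84, n1 = 8, n2 = 6)$p_raw, 2 / 3003,
               tolerance = 1e-12)
  expect_error(rank_sum_test(W = 30, n1 = 8, n2 = 6), "attainable")
  # data interface, tie-free: matches the statistic interface
  x <- c(10, 12, 14, 16, 18, 20, 22, 24); y <- c(1, 2, 3, 11, 13, 15)
  tst <- rank_sum_test(x = x, y = y)
  expect_equal(tst$method, "rank_sum_exact")
  expect_equal(tst$p_raw, rank_sum_test(W = tst$statistic, n1 = 8, n2 = 6)$p_raw)
  # oracle cross-check against base R
  expect_equal(tst$p_raw, stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("signed-rank test p-values match enumeration-derived constants", {
  expect_equal(signed_rank_test(W = 36, n = 8)$p_raw, 2 / 256)
  expect_equal(signed_rank_test(W = 35, n = 8)$p_raw, 4 / 256)
  expect_equal(signed_rank_test(W = 10, n = 6)$p_raw, 1)
  expect_error(signed_rank_test(W = 40, n = 8), "attainable")
  v <- c(0.5, 1.2, 2.1, -0.1, 3.3, 4.7, 5.1, 6.9)
  tst <- signed_rank_test(values = v)
  expect_equal(tst$p_raw, stats::wilcox.test(v, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # zeros are dropped with a note
  tz <- signed_rank_test(values = c(0, 0, 1, 2, 3, 4.5, 5.5))
  expect_match(tz$note, "2 zero")
  expect_equal(tz$n1, 5)
})

test_that("tied data falls back to a seeded Monte-Carlo permutation p", {
  x <- c(1, 2, 2, 4, 9, 12); y <- c(2, 3, 5, 6)
  a <- rank_sum_test(x = x, y = y, mc_seed = 7, mc_draws = 2e4)
  b <- rank_sum_test(x = x, y = y, mc_seed = 7, mc_draws = 2e4)
  expect_equal(a$method, "rank_sum_mc")
  expect_identical(a$p_raw, b$p_raw)
  # MC should approximate the tie-aware normal-free reference loosely
  ref <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  expect_equal(a$p_raw, ref, tolerance = 0.15)
  s <- signed_rank_test(values = c(1, -1, 2, 3, 5, 8, 13), mc_seed = 3)
  expect_equal(s$method, "signed_rank_mc")
})

test_that("two-sided p is symmetric about the null mean (tie-free)", {
  null_rs <- rank_sum_null(5, 4)
  mu <- 5 * 10 / 2
  for (W in null_rs$w)
    expect_equal(rank_sum_test(W = W, n1 = 5, n2 = 4)$p_raw,
                 rank_sum_test(W = 2 * mu - W, n1 = 5, n2 = 4)$p_raw)
  mu_sr <- 7 * 8 / 4
  for (W in 0:28)
    expect_equal(signed_rank_test(W = W, n = 7)$p_raw,
                 signed_rank_test(W = 2 * mu_sr - W, n = 7)$p_raw)
})

test_that("Bonferroni correction", {
  expect_equal(bonferroni(0.015625, 3), 0.046875)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.123, 1), 0.123)
  tst <- rank_sum_test(W = 80, n1 = 8, n2 = 6, correction_m = 3)
  expect_equal(tst$p_corrected, min(1, 3 * tst$p_raw))
  expect_error(bonferroni(0.1, 0), "m must be")
})

test_that("Spearman: monotone extremes and full permutation oracle", {
  expect_equal(spearman_corr(1:6, c(2, 5, 9, 11, 30, 31))$rho, 1)
  expect_equal(spearman_corr(1:6, -(1:6))$rho, -1)
  set.seed(61)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    got <- spearman_corr(x, y)
    rx <- rank(x); ry <- rank(y)
    perms <- lehmer_permutations(6)
    rho_all <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    expect_equal(got$rho, stats::cor(x, y, method = "spearman"))
    expect_equal(got$p, mean(abs(rho_all) >= abs(got$rho) - 1e-12))
  }
  expect_error(spearman_corr(1:3, 1:3), "n >= 4")
  big <- spearman_corr(1:20 + rnorm(20), 1:20 + rnorm(20))
  expect_equal(big$method, "t_approx")
})

test_that("exact rank-sum test is level-controlled under the null", {
  # 10^4 simulated null datasets (n = 8 vs 6): rejection rate at alpha = 0.05
  # cannot exceed alpha because the exact test is conservative by discreteness
  null <- rank_sum_null(8, 6)
  cdf <- cumsum(null$prob)
  p_of_w <- setNames(vapply(null$w, function(w) two_sided <- min(1,
    2 * min(sum(null$prob[null$w <= w]), sum(null$prob[null$w >= w]))),
    numeric(1)), null$w)
  set.seed(202)
  rejections <- vapply(1:10000, function(i) {
    W <- sum(sample.int(14, 8))
    p_of_w[[as.character(W)]] < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.05)
})
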