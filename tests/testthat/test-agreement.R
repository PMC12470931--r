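test_that("Bland-Altman reproduces hand-computed differences", {
  x <- seq(0.5, 0.9, length.out = 20)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)
  expect_equal(ba$p_mean_zero, 1)

  # d = (+0.1, -0.1) repeated 50 times
  x2 <- rep(0.7, 100)
  y2 <- x2 + rep(c(0.1, -0.1), 50)
  ba2 <- bland_altman(x2, y2)
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$sd_diff, 0.1 * sqrt(100 / 99), tolerance = 1e-12)
  expect_equal(ba2$loa_high, 1.96 * 0.1 * sqrt(100 / 99), tolerance = 1e-12)

  # constant nonzero difference: p = 0 edge
  expect_equal(bland_altman(x, x + 0.05)$p_mean_zero, 0)
  expect_error(bland_altman(c(1, 2), c(1, 2)), class = "ffrct_stats_error")
})

test_that("Bland-Altman recovers simulated bias and noise at large n", {
  set.seed(11)
  n <- 1e5
  x <- runif(n, 0.4, 0.9)
  y <- x + rnorm(n, 0.02, 0.05)
  ba <- bland_altman(x, y)
  expect_lt(abs(ba$mean_diff - 0.02), 5e-4)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * 0.05, tolerance = 0.01)
  # LOA cover about 95% of differences
  d <- y - x
  expect_equal(mean(d >= ba$loa_low & d <= ba$loa_high), 0.95,
               tolerance = 0.01)
})

test_that("Passing-Bablok handles exact linear relations", {
  x <- seq(0.1, 1, 0.1)
  pb <- passing_bablok(x, x)
  expect_equal(pb$slope, 1)
  expect_equal(pb$intercept, 0)

  # 4 points on y = 2x: all 6 pairwise slopes equal 2
  pb2 <- suppressWarnings(passing_bablok(c(0, 1, 2, 3), c(0, 2, 4, 6)))
  expect_equal(pb2$slope, 2)
  expect_equal(pb2$intercept, 0)

  expect_warning(passing_bablok(1:5, c(2, 3, 5, 7, 8)), "fewer than 10")
  expect_error(passing_bablok(rep(1, 12), rnorm(12)), class = "ffrct_stats_error")
})

test_that("Passing-Bablok matches the brute-force rank oracle", {
  set.seed(22)
  for (i in 1:15) {
    x <- round(runif(50, 0.3, 1), 3)
    y <- round(0.9 * x + 0.05 + rnorm(50, 0, 0.05), 3)
    got <- passing_bablok(x, y)
    want <- pb_bruteforce(x, y)
    expect_equal(got$slope, want$slope, tolerance = 0)
    expect_equal(got$slope_ci, want$slope_ci, tolerance = 0)
    expect_equal(got$intercept, want$intercept, tolerance = 0)
  }
})

test_that("Passing-Bablok slope is scale-equivariant", {
  set.seed(33)
  x <- runif(30, 0.3, 1)
  y <- 1.1 * x + rnorm(30, 0, 0.03)
  pb1 <- passing_bablok(x, y)
  pb2 <- passing_bablok(3 * x, 3 * y)
  expect_equal(pb2$slope, pb1$slope, tolerance = 1e-12)
  expect_equal(pb2$intercept, 3 * pb1$intercept, tolerance = 1e-12)
})

test_that("one-way ICC matches a hand ANOVA and its limit cases", {
  # hand 6x2 matrix: independent ANOVA arithmetic written out
  m <- matrix(c(0.60, 0.64, 0.72, 0.70, 0.55, 0.59,
                0.81, 0.78, 0.66, 0.66, 0.90, 0.87), ncol = 2)
  n <- 6; k <- 2
  grand <- mean(m)
  msb_hand <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msw_hand <- sum((m - rowMeans(m))^2) / (n * (k - 1))
  icc_hand <- (msb_hand - msw_hand) / (msb_hand + (k - 1) * msw_hand)
  res <- icc_oneway(m)
  expect_equal(res$icc, icc_hand, tolerance = 1e-12)
  expect_lte(res$ci_low, res$icc)
  expect_gte(res$ci_high, res$icc)

  # identical ratings per subject -> ICC 1 with degenerate CI
  perfect <- icc_oneway(cbind(1:8, 1:8))
  expect_equal(perfect$icc, 1)
  expect_equal(c(perfect$ci_low, perfect$ci_high), c(1, 1))

  # ratings independent of subject -> ICC near 0
  set.seed(44)
  noise <- matrix(rnorm(4000), ncol = 2)
  expect_equal(icc_oneway(noise)$icc, 0, tolerance = 0.05)

  expect_error(icc_oneway(matrix(1:2, 1, 2)), class = "ffrct_stats_error")
})

test_that("expected ICC interval width reproduces the sample-size case", {
  expect_equal(round_half_up(icc_ci_width(19, 2, 0.600, 0.80), 3), 0.389)
  expect_lt(icc_ci_width(19, 2, 0.999, 0.80), 0.01)
  widths <- vapply(c(10, 19, 40, 80, 160),
                   function(n) icc_ci_width(n, 2, 0.6, 0.8), 0)
  expect_true(all(diff(widths) < 0))
  expect_error(icc_ci_width(19, 2, 1.2), class = "ffrct_stats_error")
})

test_that("dropout inflation rounds up to whole cases", {
  expect_identical(inflate_for_dropout(19, 0.2), 24L)
  expect_identical(inflate_for_dropout(10, 0), 10L)
})

test_that("Spearman correlation agrees with the base-R cross-check", {
  x <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  expect_equal(spearman_cor(x, x^2)$rho, 1)
  set.seed(55)
  a <- round(runif(40, 0, 1), 2)   # ties likely
  b <- round(a + rnorm(40, 0, 0.2), 2)
  expect_equal(spearman_cor(a, b)$rho,
               suppressWarnings(cor(a, b, method = "spearman")),
               tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "ffrct_stats_error")
})

test_that("RMSE is the root mean squared difference", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
})

test_that("signed-rank test matches full enumeration and the base-R cross-check", {
  # symmetric +/- delta differences: enumeration gives p in the unit region
  d8 <- c(0.011, -0.012, 0.013, -0.014, 0.015, -0.016, 0.017, -0.018)
  ours <- wilcoxon_signed_rank(d8)
  expect_equal(ours$p, signed_rank_enum_p(d8), tolerance = 1e-12)
  expect_gt(ours$p, 0.8)

  set.seed(66)
  for (i in 1:5) {
    d <- rnorm(12, 0.2, 1)   # continuous: tie-free, exact branch applies
    ours <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_true(ours$exact)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$p, signed_rank_enum_p(d), tolerance = 1e-12)
  }
  # tied large-sample branch tracks the base-R normal approximation
  set.seed(67)
  dt <- round(rnorm(40, 0.1, 0.3), 1)
  dt <- dt[dt != 0]
  expect_equal(wilcoxon_signed_rank(dt)$p,
               suppressWarnings(wilcox.test(dt, correct = TRUE)$p.value),
               tolerance = 1e-9)
})

test_that("rank-sum test matches the base-R cross-check", {
  set.seed(77)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  ours <- wilcoxon_rank_sum(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_true(ours$exact)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  a2 <- round(rnorm(40), 1); b2 <- round(rnorm(35, 0.3), 1)
  expect_equal(wilcoxon_rank_sum(a2, b2)$p,
               suppressWarnings(wilcox.test(a2, b2, correct = TRUE)$p.value),
               tolerance = 1e-9)
})
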