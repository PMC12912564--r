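test_that("JZS t-test Bayes factor matches an independent noncentral-t oracle", {
  # oracle: marginal of the noncentral-t likelihood over a Cauchy(0, 0.707)
  # effect-size prior, computed by adaptive quadrature over the effect size
  # (a different integral than the implementation's g-parameter route)
  expect_equal(jzs_ttest_bf(2, 30, 30)$bf10, 1.371690, tolerance = 1e-4)
  expect_equal(jzs_ttest_bf(0.5, 12, 15)$bf10, 0.394606, tolerance = 1e-4)
})

test_that("JZS Bayes factor behaves monotonically and smoothly", {
  expect_lt(jzs_ttest_bf(0, 30, 30)$bf10, 1)
  ts <- seq(0, 6, by = 0.5)
  bfs <- sapply(ts, function(t) jzs_ttest_bf(t, 30, 30)$bf10)
  expect_true(all(diff(bfs) > 0))
  # no jumps near zero
  near0 <- sapply(seq(-0.01, 0.01, by = 0.001),
                  function(t) jzs_ttest_bf(t, 25, 25)$bf10)
  expect_true(all(abs(diff(near0)) / near0[-1] < 0.01))
  # one-sample form and bf10 * bf01 = 1
  b <- jzs_ttest_bf(2.5, 40)
  expect_equal(b$bf10 * b$bf01, 1, tolerance = 1e-12)
  expect_error(jzs_ttest_bf(Inf, 30, 30), "finite")
  expect_error(jzs_ttest_bf(1, 2), "n1")
})

test_that("correlation Bayes factor reproduces published JASP values", {
  expect_equal(pearson_bf(0.082, 54)$bf01, 4.98, tolerance = 0.02 * 4.98)
  expect_equal(pearson_bf(-0.005, 55)$bf01, 5.94, tolerance = 0.02 * 5.94)
  expect_equal(pearson_bf(0.132, 23)$bf01, 3.26, tolerance = 0.02 * 3.26)
  expect_equal(pearson_bf(0.058, 59)$bf01, 5.61, tolerance = 0.02 * 5.61)
  expect_gt(pearson_bf(0.86, 59)$bf10, 1000)
})

test_that("correlation Bayes factor is symmetric and sane at the null", {
  for (r in c(0.1, 0.45, 0.8)) {
    expect_equal(pearson_bf(r, 40)$bf10, pearson_bf(-r, 40)$bf10,
                 tolerance = 1e-10)
  }
  expect_gt(pearson_bf(0, 30)$bf01, 1)
  # series and Euler-integral evaluations of the hypergeometric term agree
  direct <- memprec:::hyperg_2f1(14.5, 14.5, 16, 0.49)
  via_integral <- memprec:::hyperg_2f1(14.5, 14.5, 16, 0.49, max_terms = 2)
  expect_equal(direct, via_integral, tolerance = 1e-6)
  expect_error(pearson_bf(1, 30), "degenerate")
  expect_error(pearson_bf(0.5, 3), "n")
})

test_that("rank tests give exact small-sample p-values and flag degeneracy", {
  mw <- rank_tests(c(1, 2, 3), c(4, 5, 6), mode = "mann-whitney")
  expect_equal(mw$statistic, 0)           # complete separation: U = 0
  expect_equal(mw$p, 0.1)                 # 2/20 orderings, exact two-tailed
  ident <- rank_tests(c(1, 2, 3, 4), c(1, 2, 3, 4),
                      mode = "wilcoxon-signed-rank")
  expect_true(ident$degenerate)
  expect_true(is.na(ident$p))
  set.seed(101)
  x <- rnorm(50, 3)
  y <- rnorm(50, 0)
  shift <- rank_tests(x, y, mode = "mann-whitney")
  expect_lt(shift$p, 0.001)
  pair <- rank_tests(x, y, mode = "wilcoxon-signed-rank")
  expect_lt(pair$p, 0.001)
})
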