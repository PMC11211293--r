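test_that("Bland-Altman handles constant and identical differences", {
  a <- 1:10 + 5
  ba <- bland_altman(a, 1:10)
  expect_equal(ba$bias, 5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(5, 5))
  expect_equal(ba$p_bias, 1)  # degenerate zero variance: no evidence

  same <- bland_altman(1:10, 1:10)
  expect_equal(same$bias, 0)
  expect_equal(same$p_bias, 1)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman recovers an injected bias with analytic limits of agreement", {
  set.seed(31)
  d <- rnorm(10000, mean = -20, sd = 7)
  ba <- bland_altman(d, rep(0, 10000))
  expect_gt(ba$bias, -20.5); expect_lt(ba$bias, -19.5)
  expect_lt(abs(ba$loa_low - (-20 - 1.96 * 7)), 0.5)
  expect_lt(abs(ba$loa_high - (-20 + 1.96 * 7)), 0.5)
  expect_lt(ba$p_bias, 1e-10)
  # LoA contain ~95% of differences
  inside <- mean(ba$diff >= ba$loa_low & ba$diff <= ba$loa_high)
  expect_gt(inside, 0.93); expect_lt(inside, 0.97)
  expect_equal(nrow(tidy(ba)), 1)
})

test_that("exact McNemar follows the closed binomial form", {
  expect_equal(mcnemar_exact(0, 0)$p, 1)
  expect_equal(mcnemar_exact(1, 0)$p, 1)        # 2 * 0.5 capped
  expect_equal(mcnemar_exact(10, 0)$p, 2 * 0.5^10)
  expect_error(mcnemar_exact(-1, 2), "nonnegative")
  # symmetry and monotonicity in |b - c| at fixed b + c
  set.seed(5)
  for (rep in 1:20) {
    b <- sample(0:15, 1); cc <- sample(0:15, 1)
    expect_equal(mcnemar_exact(b, cc)$p, mcnemar_exact(cc, b)$p)
  }
  total <- 12
  ps <- vapply(0:6, function(b) mcnemar_exact(b, total - b)$p, 1)
  expect_true(all(diff(ps) >= 0))  # p grows as counts balance
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("Mann-Whitney U: exact enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 2 / 6)
  expect_true(r$exact)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney U agrees with wilcox.test on tie-free samples", {
  set.seed(12)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8) + runif(1, -1, 1)
    mine <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
  }
  for (rep in 1:10) {  # normal-approximation branch
    x <- rnorm(25); y <- rnorm(30) + runif(1, -1, 1)
    mine <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Mann-Whitney U is invariant under monotone transforms", {
  set.seed(9)
  x <- rnorm(12); y <- rnorm(15) + 0.8
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(exp(x), exp(y))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)
})

test_that("Mann-Whitney U holds its type-I error rate", {
  set.seed(202)
  rej <- mean(vapply(1:1000, function(i) {
    mann_whitney_u(rnorm(15), rnorm(15))$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("Kruskal-Wallis: degenerate input, type-I error and two-group consistency", {
  kw0 <- kruskal_wallis(list(rep(2, 5), rep(2, 4), rep(2, 6)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 nonempty")

  set.seed(303)
  rej <- mean(vapply(1:1000, function(i) {
    kruskal_wallis(list(rnorm(10), rnorm(10), rnorm(10)))$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)

  # two groups: same rejection decision as Mann-Whitney at alpha = 0.05
  set.seed(404)
  for (rep in 1:100) {
    x <- rnorm(25); y <- rnorm(25)
    expect_equal(kruskal_wallis(list(x, y))$p < 0.05,
                 mann_whitney_u(x, y)$p < 0.05)
  }
})

test_that("Wald proportion intervals clip to [0, 100]", {
  ci <- wald_ci(176, 178)
  expect_equal(ci[2], 100)            # upper bound clips
  expect_gt(ci[1], 97.0); expect_lt(ci[1], 97.6)
  expect_equal(wald_ci(10, 10), c(100, 100))
  expect_equal(wald_ci(0, 10), c(0, 0))  # documented Wald degeneracy
  expect_error(wald_ci(5, 4), "0 <= k <= n")
})
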