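test_that("pearson_cor matches the product-moment definition and its t-based p", {
  # perfect positive and negative linearity
  expect_equal(pearson_cor(1:10, 1:10)$r, 1)
  expect_equal(pearson_cor(1:10, -2 * (1:10) + 7)$r, -1)

  # hand-evaluated: x=(1,2,3,4), y=(1,3,2,5): Sxy=5.5, Sxx=5, Syy=8.75
  res <- pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 5))
  expect_equal(res$r, 5.5 / sqrt(5 * 8.75))
  ref <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 5))
  expect_equal(res$p_value, ref$p.value)

  # missing pairs dropped; n counts complete pairs only
  res <- pearson_cor(c(1, 2, NA, 4, 5), c(2, NA, 3, 8, 10))
  expect_equal(res$n, 3L)
})

test_that("pearson_cor degenerate inputs are not computable, never an error", {
  expect_false(pearson_cor(c(1, 2), c(3, 4))$computable)
  expect_false(pearson_cor(rep(1, 5), 1:5)$computable)
  expect_false(pearson_cor(1:5, rep(2, 5))$computable)
})

test_that("shapiro_wilk reproduces the reference implementation", {
  # stats::shapiro.test implements the same published algorithm and serves
  # as the independent reference
  set.seed(42)
  for (n in c(4, 5, 7, 11, 12, 20, 100, 800)) {
    x <- rnorm(n)
    mine <- shapiro_wilk(x)
    ref <- shapiro.test(x)
    expect_equal(mine$W, unname(ref$statistic), tolerance = 1e-4)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-4)
    # order invariance
    expect_equal(shapiro_wilk(sample(x))$W, mine$W)
  }
  skew <- rexp(20, 0.3)^2
  expect_equal(shapiro_wilk(skew)$p_value, shapiro.test(skew)$p.value,
               tolerance = 1e-4)
})

test_that("shapiro_wilk detects heavy-tailed data and flags constants", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- rt(500, df = 2)
    hits <- hits + (shapiro_wilk(x)$p_value < 0.05)
  }
  expect_gte(hits, 95)
  expect_false(shapiro_wilk(rep(3, 10))$computable)
})

test_that("mann_whitney exact path agrees with enumeration identities", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3)  # 2 of C(4,2)=6 assignments as extreme
  expect_identical(res$method, "exact")

  # identical multisets: U = n1*n2/2 by symmetry (tied, so approx path)
  res <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(res$U, 4.5)

  set.seed(7)
  for (i in 1:10) {
    x <- runif(sample(3:6, 1)); y <- runif(sample(3:6, 1))
    mine <- mann_whitney(x, y)
    expect_identical(mine$method, "exact")
    expect_equal(mine$p_value, oracle_mw_exact_p(x, y))
  }
})

test_that("mann_whitney normal approximation matches the tie-corrected form", {
  set.seed(11)
  for (i in 1:10) {
    x <- sample(0:9, 25, replace = TRUE)
    y <- sample(0:9, 30, replace = TRUE) + (i %% 3)
    mine <- mann_whitney(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value)
  }
})

test_that("approximate Mann-Whitney p is close to a permutation oracle", {
  set.seed(99)
  x <- rnorm(30); y <- rnorm(30) + 0.8
  approx_p <- mann_whitney(x, y)$p_value
  # permutation oracle on U in chunks
  r <- rank(c(x, y)); nn <- 60; n1 <- 30
  U_obs <- sum(r[1:30]) - n1 * (n1 + 1) / 2
  mu <- n1 * 30 / 2
  B <- 1e6; extreme <- 0
  set.seed(100)
  for (chunk in 1:100) {
    us <- replicate(B / 100, sum(r[sample.int(nn, n1)]) - n1 * (n1 + 1) / 2)
    extreme <- extreme + sum(abs(us - mu) >= abs(U_obs - mu) - 1e-9)
  }
  expect_lt(abs(approx_p - extreme / B), 0.005)
})

test_that("compare_groups gates on Shapiro-Wilk and records the route", {
  set.seed(1)
  # clean normal samples route to the t test
  routes <- replicate(30, {
    compare_groups(rnorm(20), rnorm(20))$test_used
  })
  expect_gt(mean(routes == "t_test"), 0.8)

  # a strongly bimodal group fires the gate
  set.seed(2)
  routes <- replicate(30, {
    x <- c(rnorm(12, -4, 0.3), rnorm(12, 4, 0.3))
    compare_groups(x, rnorm(24))$test_used
  })
  expect_true(all(routes == "mann_whitney"))

  # identical lists: p ~ 1 whichever route
  expect_gt(compare_groups(1:10, 1:10)$p_value, 0.9)
})

test_that("t_test_unpaired matches stats::t.test in both variants", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(15, 0.5, 2)
  mine <- t_test_unpaired(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
  mine_w <- t_test_unpaired(x, y, welch = TRUE)
  ref_w <- t.test(x, y)
  expect_equal(mine_w$df, unname(ref_w$parameter))
  expect_equal(mine_w$p_value, ref_w$p.value)
})

test_that("bland_altman computes bias and limits of agreement by definition", {
  res <- bland_altman(c(1, 2, 3), c(2, 2, 2))
  expect_equal(res$bias, 0)
  expect_equal(res$loa_low, -1.96)
  expect_equal(res$loa_high, 1.96)

  # identity pair
  res <- bland_altman(1:5, 1:5)
  expect_equal(c(res$bias, res$loa_low, res$loa_high), c(0, 0, 0))

  # translation equivariance and pair-swap antisymmetry
  set.seed(8)
  a <- rnorm(20); b <- rnorm(20)
  base <- bland_altman(a, b)
  shift <- bland_altman(a + 3, b)
  expect_equal(shift$bias, base$bias + 3)
  expect_equal(shift$loa_low, base$loa_low + 3)
  expect_equal(shift$loa_high, base$loa_high + 3)
  swap <- bland_altman(b, a)
  expect_equal(swap$bias, -base$bias)
  expect_equal(swap$loa_low, -base$loa_high)
  expect_equal(swap$loa_high, -base$loa_low)

  # LOA symmetric around bias
  expect_equal(base$loa_high - base$bias, base$bias - base$loa_low)
  expect_false(bland_altman(c(1, 2), c(1, 1))$computable)
})

test_that("compare_groups holds its nominal size under the null", {
  set.seed(123)
  rej <- 0
  nsim <- 400
  for (i in seq_len(nsim)) {
    rej <- rej + (compare_groups(rnorm(15), rnorm(15))$p_value < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / nsim)
  expect_gte(rej / nsim, 0.05 - 2.5 * se)
  expect_lte(rej / nsim, 0.05 + 2.5 * se)
})
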