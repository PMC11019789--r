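# Rank-test primitives against closed forms and independent oracles.

test_that("Mann-Whitney exact p matches enumeration-based oracles", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_identical(mw$method, "exact")
  # identical multisets -> p = 1 on the enumeration grid
  expect_equal(mann_whitney_u(c(2, 5, 9), c(2, 5, 9))$p, 1)
  # independent oracle: wilcox.test exact p on untied data
  set.seed(71)
  for (i in 1:10) {
    pool <- sample(1000, 11)
    a <- pool[1:5]; b <- pool[6:11]
    expect_equal(mann_whitney_u(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("normal approximation tracks the exact Mann-Whitney p", {
  set.seed(73)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    p_exact <- mann_whitney_u(a, b)$p
    p_norm <- mann_whitney_u(a, b, exact_max = 0L)$p
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("Kruskal-Wallis H matches the hand value and stats oracle", {
  kw <- kruskal_wallis(1:6, rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 3.857, tolerance = 5e-4)
  expect_equal(kw$H,
               unname(kruskal.test(list(1:3, 4:6))$statistic),
               tolerance = 1e-10)
  expect_equal(kruskal_wallis(rep(5, 6), rep(c("a", "b"), 3))$H, 0)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 classes")
  # chi-squared path agrees with stats::kruskal.test including ties
  set.seed(79)
  for (i in 1:10) {
    v <- sample(10, 15, replace = TRUE)
    g <- sample(rep(c("a", "b", "c"), 5))
    mine <- kruskal_wallis(v, g)
    ref <- kruskal.test(v, factor(g))
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("two-class Kruskal-Wallis orders p like the rank-sum test", {
  set.seed(83)
  p_kw <- p_mw <- numeric(100)
  for (i in 1:100) {
    a <- rnorm(8, sd = 2); b <- rnorm(7, mean = runif(1, 0, 2))
    p_kw[i] <- kruskal_wallis(c(a, b), rep(c("a", "b"), c(8, 7)))$p
    p_mw[i] <- mann_whitney_u(a, b, exact_max = 0L)$p
  }
  # both p-values are monotone in the same rank-sum deviation, so they
  # order any two datasets identically (up to floating-point ties)
  d_kw <- outer(p_kw, p_kw, "-")
  d_mw <- outer(p_mw, p_mw, "-")
  decided <- abs(d_kw) > 1e-9 & abs(d_mw) > 1e-9
  expect_true(all(sign(d_kw[decided]) == sign(d_mw[decided])))
})

test_that("Kruskal-Wallis p is invariant under monotone transforms", {
  set.seed(89)
  v <- rlnorm(12); g <- rep(c("a", "b", "c"), 4)
  base <- kruskal_wallis(v, g)
  for (f in list(log, sqrt, function(x) x^3, function(x) 10 * x + 2)) {
    tr <- kruskal_wallis(f(v), g)
    expect_equal(tr$H, base$H, tolerance = 1e-12)
    expect_equal(tr$p, base$p, tolerance = 1e-12)
  }
})

test_that("Spearman permutation test: exact enumeration and extremes", {
  sp <- spearman_perm(1:5, c(2, 4, 6, 8, 10))
  expect_equal(sp$r, 1)
  expect_equal(sp$p, 2 / 120)
  expect_identical(sp$method, "exact")
  expect_equal(spearman_perm(1:6, 6:1)$r, -1)
  # independent oracle: cor.test exact Spearman p (no ties)
  set.seed(97)
  for (i in 1:8) {
    x <- rnorm(6); y <- rnorm(6)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    mine <- spearman_perm(x, y)
    expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ct$p.value, tolerance = 1e-12)
  }
  # constant series: degenerate, never significant
  dg <- spearman_perm(rep(1, 6), 1:6)
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
})

test_that("exact Spearman enumeration agrees with Monte-Carlo at n = 6", {
  set.seed(101)
  x <- rnorm(6); y <- x + rnorm(6)
  p_exact <- spearman_perm(x, y)$p
  B <- 4000
  r_obs <- cor(rank(x), rank(y))
  hits <- sum(replicate(B, abs(cor(rank(x), rank(sample(y)))) >= abs(r_obs) - 1e-9))
  p_mc <- hits / B
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(p_exact - p_mc), 3 * se + 1e-6)
})

test_that("BH q-values match the step-up formula and stats oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(103)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_equal(order(q[order(p)]), seq_along(p))  # order-preserving
  }
})
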