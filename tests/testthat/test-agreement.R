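test_that("ICC(A,1) reproduces the worked offset-rater table", {
  tab <- cbind(r1 = c(1, 3, 5, 7), r2 = c(2, 4, 6, 8))
  res <- icc_absolute_agreement(tab)
  # by hand: MSR = 40/3, MSC = 2, MSE = 0 -> ICC = (40/3) / (40/3 + 1) = 40/43
  expect_equal(res$msr, 40 / 3, tolerance = 1e-12)
  expect_equal(res$msc, 2, tolerance = 1e-12)
  expect_equal(res$mse, 0, tolerance = 1e-12)
  expect_equal(res$icc, 40 / 43, tolerance = 1e-12)
})

test_that("ICC(A,1) matches the aov mean-squares oracle on random tables", {
  set.seed(1234)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    k <- sample(2:3, 1)
    tab <- matrix(sample(1:5, n * k, replace = TRUE), n, k)
    if (stats::var(rowMeans(tab)) == 0) next
    expect_equal(icc_absolute_agreement(tab)$icc, aov_icc_a1(tab),
                 tolerance = 1e-10)
  }
})

test_that("identical columns give ICC 1 and offsets reduce agreement", {
  tab <- cbind(c(2, 4, 6, 9), c(2, 4, 6, 9))
  res <- icc_absolute_agreement(tab)
  expect_equal(res$icc, 1)
  shifted <- tab
  shifted[, 2] <- shifted[, 2] + 3
  expect_lt(icc_absolute_agreement(shifted)$icc, 1)
})

test_that("ICC is scale invariant and its CI brackets the estimate", {
  set.seed(77)
  true <- rnorm(12, 100, 20)
  tab <- cbind(true + rnorm(12, 0, 5), true + rnorm(12, 0, 8),
               true + 2 + rnorm(12, 0, 6))
  r1 <- icc_absolute_agreement(tab)
  r2 <- icc_absolute_agreement(tab * 3.7)
  expect_equal(r1$icc, r2$icc, tolerance = 1e-12)
  expect_lte(r1$lower, r1$icc)
  expect_gte(r1$upper, r1$icc)
})

test_that("degenerate ratings tables raise the dedicated error", {
  flat <- cbind(c(5, 5, 5), c(5, 5, 5))
  expect_error(icc_absolute_agreement(flat), class = "stereovol_degenerate_table")
  expect_error(icc_absolute_agreement(cbind(1:3)), "raters")
  expect_error(icc_absolute_agreement(rbind(c(1, 2))), "subjects")
})

test_that("two-group ANOVA matches hand arithmetic and base R", {
  res <- anova_between(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 13.5, tolerance = 1e-12)
  expect_equal(res$df, c(1, 4))

  same <- anova_between(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # cross-check against stats::aov on random data
  set.seed(8)
  for (rep in 1:10) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), mean = 0.5)
    res <- anova_between(a, b)
    long <- data.frame(y = c(a, b),
                       g = factor(rep(1:2, c(length(a), length(b)))))
    ref <- summary(stats::aov(y ~ g, data = long))[[1]]
    expect_equal(res$statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(res$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("F equals the square of the pooled t statistic", {
  set.seed(15)
  for (rep in 1:20) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1), 1)
    f <- anova_between(a, b)$statistic
    t <- two_sample_t(a, b)$statistic
    expect_equal(f, t^2, tolerance = 1e-10)
  }
})

test_that("t test symmetry and degenerate cases behave per contract", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r1 <- two_sample_t(a, b); r2 <- two_sample_t(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic^2, 13.5, tolerance = 1e-12)

  expect_equal(two_sample_t(c(1, 1), c(1, 1))$statistic, 0)
  zerovar <- anova_between(c(2, 2), c(3, 3))
  expect_true(zerovar$degenerate)
  expect_equal(zerovar$p_value, 0)
  expect_equal(zerovar$statistic, Inf)
})

test_that("asymmetry index is exact, antisymmetric and bounded", {
  expect_equal(asymmetry_index(100, 100), 0)
  expect_equal(asymmetry_index(110, 90), 20)
  set.seed(5)
  l <- runif(100, 1, 1000); r <- runif(100, 1, 1000)
  expect_equal(asymmetry_index(l, r), -asymmetry_index(r, l))
  ai <- asymmetry_index(l, r)
  expect_true(all(ai > -200 & ai < 200))
  expect_error(asymmetry_index(-1, 5), "positive")
})

test_that("p-value adjustment follows Bonferroni and Holm", {
  expect_equal(adjust_pvalues(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(adjust_pvalues(0.03), 0.03)
  p <- c(0.01, 0.04, 0.03)
  # hand enumeration: Holm sorted (0.01, 0.03, 0.04) -> (0.03, 0.06, 0.06)
  expect_equal(adjust_pvalues(p, "holm"), c(0.03, 0.06, 0.06))
  expect_true(all(adjust_pvalues(p, "holm") <= adjust_pvalues(p, "bonferroni")))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})
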