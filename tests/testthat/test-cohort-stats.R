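test_that("subgroup percentages use half-up rounding", {
  expect_equal(subgroup_percentage(23, 25), 92)
  expect_equal(subgroup_percentage(72, 186), 39)  # 38.7 rounds up
  expect_equal(subgroup_percentage(14, 186), 8)   # 7.53 rounds up
  expect_equal(subgroup_percentage(20, 64), 31)   # 31.25 rounds down
  expect_equal(subgroup_percentage(0, 10), 0)
  expect_error(subgroup_percentage(1, 0), "positive")
  expect_error(subgroup_percentage(11, 10), "count")
})

test_that("normality tests pass Gaussian data and reject skewed data", {
  set.seed(51)
  norm_ok <- c(shapiro = 0L, lillie = 0L)
  exp_rej <- c(shapiro = 0L, lillie = 0L)
  for (s in 1:100) {
    g <- rnorm(500)
    e <- rexp(500)
    norm_ok["shapiro"] <- norm_ok["shapiro"] +
      (normality_test(g, "shapiro_wilk") > 0.05)
    norm_ok["lillie"] <- norm_ok["lillie"] +
      (normality_test(g, "lilliefors") > 0.05)
    exp_rej["shapiro"] <- exp_rej["shapiro"] +
      (normality_test(e, "shapiro_wilk") < 0.05)
    exp_rej["lillie"] <- exp_rej["lillie"] +
      (normality_test(e, "lilliefors") < 0.05)
  }
  expect_gte(min(norm_ok), 90L) # nominal 95% pass rate with MC slack
  expect_gte(min(exp_rej), 95L) # n=500 exponential: essentially always rejected
  expect_error(normality_test(rep(1, 10)), "constant")
  expect_error(normality_test(c(1, 2, 3)), "n >= 4")
})

test_that("continuous comparisons gate between parametric and nonparametric branches", {
  set.seed(52)
  # two clean Gaussian samples -> t branch
  r <- compare_continuous(list(rnorm(40), rnorm(40, 0.2)))
  expect_equal(r$test_used, "t")
  # heavy-tailed samples -> Mann-Whitney
  r2 <- compare_continuous(list(rexp(40), rexp(40)))
  expect_equal(r2$test_used, "mann_whitney")
  # groups too small to normality-test fall through to the exact MW branch
  r3 <- compare_continuous(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r3$test_used, "mann_whitney")
  expect_equal(r3$p_value, 0.1)
  # >2 groups
  r4 <- compare_continuous(list(rnorm(30), rnorm(30), rnorm(30)))
  expect_equal(r4$test_used, "anova")
  r5 <- compare_continuous(list(rexp(30), rexp(30), rexp(30)))
  expect_equal(r5$test_used, "kruskal_wallis")
  expect_error(compare_continuous(list(rnorm(10))), ">= 2 groups")
})

test_that("the normality gate is a pure function of its inputs", {
  set.seed(53)
  g <- list(rnorm(25), rexp(25))
  a <- compare_continuous(g)
  b <- compare_continuous(g)
  expect_identical(a$test_used, b$test_used)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$gate, b$gate)
})

test_that("parametric-branch p-values are calibrated under the null", {
  set.seed(54)
  ps <- replicate(60, {
    r <- compare_continuous(list(rnorm(30), rnorm(30)))
    if (r$test_used == "t") r$p_value else NA
  })
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 30)
  # roughly uniform: rejection rate near 5%
  expect_lt(mean(ps < 0.05), 0.18)
  expect_gt(mean(ps > 0.5), 0.25)
})

test_that("contingency tests pick Fisher for sparse 2x2 tables and chi-square otherwise", {
  f <- contingency_test(matrix(c(3, 0, 0, 3), 2, 2))
  expect_equal(f$test_used, "fisher")
  expect_equal(f$p_value, 0.1, tolerance = 1e-12)

  c1 <- contingency_test(matrix(10, 2, 2))
  expect_equal(c1$test_used, "chi_square")
  expect_equal(c1$p_value, 1)

  # all expected >= 5: chi-square with continuity correction, checked against
  # the closed-form corrected statistic and chi-square tail
  tab <- matrix(c(18, 7, 9, 16), 2, 2)
  r <- contingency_test(tab)
  expect_equal(r$test_used, "chi_square")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - e) - 0.5)^2 / e)
  expect_equal(r$p_value, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(contingency_test(matrix(c(0, 0, 1, 2), 2, 2)), "zero margin")
  expect_error(contingency_test(matrix(c(1.5, 1, 1, 1), 2, 2)), "integers")
})

test_that("Fisher p equals hypergeometric enumeration on random sparse tables", {
  set.seed(55)
  for (rep in 1:100) {
    tab <- matrix(rpois(4, 3), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    r <- contingency_test(tab)
    if (r$test_used != "fisher") next
    expect_equal(r$p_value, oracle_fisher_p(tab), tolerance = 1e-9)
  }
})
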