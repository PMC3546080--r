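test_that("describe returns mean and n-1 standard deviation", {
  expect_equal(describe(c(2, 2, 2))[["sd"]], 0)
  x <- c(1, 2, 3, 4)
  d <- describe(x)
  expect_equal(d[["mean"]], 2.5)
  expect_equal(d[["sd"]], sqrt(sum((x - 2.5)^2) / 3))
  expect_error(describe(1), "at least 2")
})

test_that("welch_from_summary matches a raw-data Welch test with identical summaries", {
  set.seed(8)
  x <- rnorm(20, 5, 2); y <- rnorm(18, 3, 1)
  raw <- t.test(x, y, var.equal = FALSE)
  summ <- welch_from_summary(mean(x), sd(x), 20, mean(y), sd(y), 18)
  expect_equal(summ$statistic, unname(raw$statistic), tolerance = 1e-9)
  expect_equal(summ$df, unname(raw$parameter), tolerance = 1e-9)
  expect_equal(summ$p_value, raw$p.value, tolerance = 1e-9)
  eq <- welch_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(welch_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("test dispatch follows the normality screen", {
  set.seed(31)
  r <- dispatch_test(rnorm(200), rnorm(200) + 3)
  expect_equal(r$test_used, "t_welch")
  expect_lt(r$p_value, 1e-6)
  # heavily skewed samples must take the rank branch (checked over seeds)
  branches <- sapply(1:20, function(s) {
    set.seed(s)
    dispatch_test(rexp(50), rexp(50) * 1.5)$test_used
  })
  expect_true(all(branches == "mann_whitney"))
  # identical groups are not significant
  z <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(dispatch_test(z, z)$p_value, 1)
  expect_error(dispatch_test(1, c(1, 2)), "at least 2")
  const <- rep(2, 6)
  expect_message(rc <- dispatch_test(const, const), "degenerate")
  expect_equal(rc$p_value, 1)
})

test_that("Mann-Whitney p agrees with exhaustive rank-sum enumeration", {
  # groups below the normality screen's minimum size dispatch to the rank
  # branch with exact enumeration
  set.seed(17)
  for (i in 1:8) {
    x <- round(runif(sample(3:4, 1), 0, 100), 3)
    y <- round(runif(sample(3:4, 1), 20, 120), 3)
    got <- dispatch_test(x, y)
    expect_equal(got$test_used, "mann_whitney")
    expect_equal(got$p_value, oracle_mann_whitney_p(x, y), tolerance = 1e-9)
  }
})

test_that("one-variable Wilks' lambda equals the within/total sum-of-squares ratio", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(30)
    grp <- rep(c("a", "b"), 15)
    ssw <- sum(tapply(x, grp, function(v) sum((v - mean(v))^2)))
    sst <- sum((x - mean(x))^2)
    expect_equal(wilks_lambda(data.frame(x), grp), ssw / sst,
                 tolerance = 1e-12)
  }
})

test_that("stepwise LDA separates, selects, and is affine invariant", {
  # perfectly separated 1-D groups
  d <- data.frame(v = c(rnorm(15, 0, 0.1), rnorm(15, 10, 0.1)))
  g <- rep(c("a", "b"), each = 15)
  res <- stepwise_lda(d, g)
  expect_equal(res$selected_variables, "v")
  expect_lt(res$wilks_lambda, 0.05)
  expect_equal(res$accuracy_overall, 100)
  expect_equal(sum(res$confusion), 30)

  # identical groups: empty selection, majority-class accuracy
  set.seed(2)
  noise <- rnorm(30)
  res0 <- stepwise_lda(data.frame(a = noise, b = noise * 2), g)
  expect_length(res0$selected_variables, 0)

  # rescaling a variable does not change the classification
  set.seed(4)
  d2 <- data.frame(x = c(rnorm(20, 0), rnorm(20, 2)),
                   y = c(rnorm(20, 1), rnorm(20, 1.5)))
  g2 <- rep(c("a", "b"), each = 20)
  r1 <- stepwise_lda(d2, g2)
  d3 <- data.frame(x = d2$x * 1000 - 7, y = d2$y)
  r2 <- stepwise_lda(d3, g2)
  expect_equal(r2$accuracy_overall, r1$accuracy_overall)
  expect_equal(r2$wilks_lambda, r1$wilks_lambda, tolerance = 1e-9)
})

test_that("cohort simulation respects moments, truncation and the seed", {
  summ <- list(grp = list(v = c(5, 0)))
  d0 <- simulate_cohort(summ, c(grp = 10), seed = 1)
  expect_true(all(d0$v == 5))

  summ2 <- list(grp = list(v = c(3, 1)))
  big <- simulate_cohort(summ2, c(grp = 1e5), seed = 2)
  expect_equal(mean(big$v), 3, tolerance = 0.01 * 3)
  expect_true(all(big$v >= 0))

  a <- simulate_cohort(summ2, c(grp = 50), seed = 9)
  b <- simulate_cohort(summ2, c(grp = 50), seed = 9)
  expect_identical(a, b)
  expect_error(simulate_cohort(summ2, c(grp = -1)), "non-negative")
})
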