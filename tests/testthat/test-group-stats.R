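test_that("Mann-Whitney exact p matches full enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  # property: all tie-free random samples with combined n <= 10
  set.seed(41)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(seq_len(50), n1 + n2)  # distinct integers: no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    r <- mann_whitney_u(x, y)
    expect_true(r$exact)
    expect_equal(r$p_value, mw_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles symmetry, ties and degeneracy", {
  x <- c(1.2, 5.4, 2.2, 8); y <- c(3.1, 0.4, 9.9)
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value,
               tolerance = 1e-12)
  same <- c(2, 5, 7, 8)
  expect_equal(mann_whitney_u(same, same)$p_value, 1)
  deg <- mann_whitney_u(rep(3, 4), rep(3, 5))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  # ties or large n fall back to the corrected normal approximation
  tied <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 4, 4))
  expect_false(tied$exact)
  expect_true(tied$p_value > 0 && tied$p_value <= 1)
  big <- mann_whitney_u(rnorm(20), rnorm(20))
  expect_false(big$exact)
})

test_that("exact Mann-Whitney is calibrated under the null", {
  set.seed(2026)
  n_sim <- 2000
  rej <- vapply(seq_len(n_sim), function(i) {
    mann_whitney_u(rnorm(7), rnorm(7))$p_value <= 0.05
  }, logical(1))
  rate <- mean(rej)
  mc_se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(rate, 0.05 + 3 * mc_se)
})

test_that("pooled-variance t-test reproduces the textbook formula", {
  r <- students_t(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r$statistic, -2.449, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-abs(r$statistic), 4), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0705, tolerance = 1e-3)
  # agreement with the base implementation on arbitrary data
  set.seed(7)
  x <- rnorm(9, 1); y <- rnorm(12)
  base <- t.test(x, y, var.equal = TRUE)
  mine <- students_t(x, y)
  expect_equal(mine$statistic, unname(base$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, base$p.value, tolerance = 1e-12)
  # equal samples and scale equivariance
  expect_equal(students_t(x, x)$statistic, 0)
  expect_equal(students_t(x, x)$p_value, 1)
  expect_equal(students_t(5 * x, 5 * y)$statistic, mine$statistic,
               tolerance = 1e-12)
  deg <- students_t(rep(2, 3), rep(3, 3))
  expect_true(deg$degenerate)
})

test_that("one-way ANOVA matches the hand decomposition and base R", {
  r <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8)))
  expect_equal(r$statistic, 21, tolerance = 1e-12)
  expect_equal(r$p_value, 1 / 512, tolerance = 1e-9)  # (1 + 2F/6)^-3 for F(2,6)
  g <- list(rnorm(5, 1), rnorm(7), rnorm(6, 0.5))
  set.seed(11)
  g <- lapply(g, jitter)
  base <- anova(lm(unlist(g) ~ factor(rep(seq_along(g), lengths(g)))))
  mine <- one_way_anova(g)
  expect_equal(mine$statistic, base$`F value`[1], tolerance = 1e-9)
  expect_equal(mine$p_value, base$`Pr(>F)`[1], tolerance = 1e-9)
  ident <- one_way_anova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("F equals t squared for two groups", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(4 + i); y <- rnorm(6, 0.3)
    f <- one_way_anova(list(x, y))$statistic
    t <- students_t(x, y)$statistic
    expect_equal(f, t^2, tolerance = 1e-9)
  }
})

test_that("percent change follows the reporting convention", {
  expect_equal(percent_change(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(percent_change(0.051, 0.1), -49, tolerance = 1e-12)
  expect_equal(percent_change(0.143, 0.1), 43, tolerance = 1e-12)
  expect_error(percent_change(1, c(-1, 1)), "zero")
  # a multiplicative effect c maps to 100(c-1), its inverse to 100(1/c - 1)
  x <- c(2, 3, 5)
  for (c_ in c(0.5, 1.7)) {
    expect_equal(percent_change(c_ * x, x), 100 * (c_ - 1), tolerance = 1e-12)
    expect_equal(percent_change(x, c_ * x), 100 * (1 / c_ - 1), tolerance = 1e-12)
  }
})

test_that("sample summaries use the n-1 denominator and flag n = 1", {
  s <- summarize_sample(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 1.2910, tolerance = 1e-4)
  expect_equal(s$n, 4L)
  s1 <- summarize_sample(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sd))
  expect_equal(summarize_sample(rep(2, 6))$sd, 0)
})

test_that("two-condition comparisons bundle summaries, change and test", {
  ctl <- c(0.09, 0.11, 0.10, 0.12, 0.08)
  trt <- c(0.05, 0.06, 0.04, 0.05)
  cmp <- compare_groups(ctl, trt, labels = c("control", "knockdown"))
  expect_equal(cmp$ns, c(5L, 4L))
  expect_equal(cmp$means[1], mean(ctl))
  expect_equal(cmp$percent_change, 100 * (mean(trt) - mean(ctl)) / mean(ctl))
  expect_equal(cmp$p_value, mann_whitney_u(trt, ctl)$p_value)
  expect_output(print(cmp), "knockdown")
  cmp_t <- compare_groups(ctl, trt, test = "t")
  expect_equal(cmp_t$p_value, students_t(trt, ctl)$p_value)
})
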