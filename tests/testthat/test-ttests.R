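test_that("unpaired t-test reproduces hand-computed examples", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  r <- t_unpaired(x, y)
  expect_equal(r$statistic, -1)  # mean diff -1, pooled sd sqrt(2.5), se 1
  expect_equal(r$df, 8)
  expect_false(r$reject)

  same <- t_unpaired(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # Student and Welch coincide for equal n and equal sample variances
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  st <- t_unpaired(a, b, welch = FALSE)
  we <- t_unpaired(a, b, welch = TRUE)
  expect_equal(st$statistic, we$statistic)
  expect_equal(st$df, we$df)
  expect_equal(st$p_value, we$p_value)
})

test_that("paired t-test reproduces hand-computed examples", {
  x <- c(3, 2, 4, 2); y <- c(1, 2, 2, 2)  # differences 2, 0, 2, 0
  r <- t_paired(x, y)
  expect_equal(r$statistic, sqrt(3))  # mean 1, sd 2/sqrt(3), se 1/sqrt(3)
  expect_equal(r$df, 3)
  oracle <- stats::t.test(x, y, paired = TRUE)
  expect_equal(r$p_value, oracle$p.value, tolerance = 1e-12)

  expect_equal(t_paired(x, x)$p_value, 1)
  expect_error(t_paired(1:3, 1:4), "equal length")
})

test_that("degenerate constant samples follow the stated conventions", {
  # both samples constant, equal means -> p = 1
  expect_equal(t_unpaired(rep(2, 5), rep(2, 7))$p_value, 1)
  # both samples constant, unequal means -> p = 0, infinite statistic
  r <- t_unpaired(rep(2, 5), rep(3, 7), welch = TRUE)
  expect_equal(r$p_value, 0)
  expect_true(is.infinite(r$statistic))
  expect_true(r$reject)
  # constant differences with nonzero mean
  expect_equal(t_paired(c(2, 3, 4), c(1, 2, 3))$p_value, 0)
})

test_that("p-values, statistics and df match stats::t.test on random inputs", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    x <- stats::rnorm(n1, sd = stats::runif(1, 0.5, 2))
    y <- stats::rnorm(n2, mean = stats::runif(1, -1, 1))
    st <- t_unpaired(x, y, welch = FALSE)
    ot <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(st$statistic, unname(ot$statistic), tolerance = 1e-10)
    expect_equal(st$p_value, ot$p.value, tolerance = 1e-10)
    we <- t_unpaired(x, y, welch = TRUE)
    ow <- stats::t.test(x, y)
    expect_equal(we$df, unname(ow$parameter), tolerance = 1e-10)
    expect_equal(we$p_value, ow$p.value, tolerance = 1e-10)
    if (n1 == n2) {
      pa <- t_paired(x, y)
      op <- stats::t.test(x, y, paired = TRUE)
      expect_equal(pa$p_value, op$p.value, tolerance = 1e-10)
    }
  }
})

test_that("column-vectorized tests agree with the scalar implementations", {
  set.seed(43)
  A <- matrix(stats::rnorm(30 * 50), 30)
  B <- matrix(stats::rnorm(40 * 50, 0.3), 40)
  for (welch in c(FALSE, TRUE)) {
    pv <- ilrpower:::.t_cols_unpaired(A, B, welch)
    ps <- vapply(1:50, function(j)
      t_unpaired(A[, j], B[, j], welch = welch)$p_value, numeric(1))
    expect_equal(pv, ps, tolerance = 1e-9)
  }
  pv <- ilrpower:::.t_cols_paired(A, B[1:30, ])
  ps <- vapply(1:50, function(j) t_paired(A[, j], B[1:30, j])$p_value, numeric(1))
  expect_equal(pv, ps, tolerance = 1e-9)
})

test_that("all variants hold their size under a normal null", {
  set.seed(44)
  R <- 2000; n <- 30
  band <- 3 * sqrt(0.05 * 0.95 / R)
  A <- matrix(stats::rnorm(n * R), n)
  B <- matrix(stats::rnorm(n * R), n)
  expect_lt(abs(mean(ilrpower:::.t_cols_unpaired(A, B, FALSE) < 0.05) - 0.05), band)
  expect_lt(abs(mean(ilrpower:::.t_cols_unpaired(A, B, TRUE) < 0.05) - 0.05), band)
  expect_lt(abs(mean(ilrpower:::.t_cols_paired(A, B) < 0.05) - 0.05), band)
})

test_that("significance level is validated and drives the rejection flag", {
  expect_error(t_unpaired(1:5, 2:6, alpha = 0), "alpha")
  expect_error(t_paired(1:5, 2:6, alpha = 1), "alpha")
  r <- t_unpaired(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10), alpha = 0.001)
  expect_identical(r$reject, r$p_value < 0.001)
})
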