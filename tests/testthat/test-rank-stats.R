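test_that("median_iqr reports order-statistic medians with a recorded convention", {
  s <- median_iqr(c(5))
  expect_equal(c(s$median, s$p25, s$p75), c(5, 5, 5))
  expect_equal(s$n, 1)

  s <- median_iqr(c(1, 2, 3, 10))
  expect_equal(s$median, 2.5)
  expect_lte(s$p25, s$median)
  expect_gte(s$p75, s$median)
  expect_equal(s$quantile_type, 7)

  # conventions differ and are recorded, not hidden
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  s7 <- median_iqr(x, type = 7)
  s6 <- median_iqr(x, type = 6)
  expect_equal(s7$p25, quantile(x, 0.25, type = 7, names = FALSE))
  expect_equal(s6$p25, quantile(x, 0.25, type = 6, names = FALSE))
  expect_equal(s6$quantile_type, 6)
  expect_equal(s6$median, s7$median)

  expect_error(median_iqr(numeric(0)), "non-empty")
})

test_that("the exact Mann-Whitney tail matches direct enumeration on a worked case", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$method, "exact")
  # 1 of the 6 equally likely group assignments is as extreme in each tail
  expect_equal(res$p_two_sided, 2 / 6)
})

test_that("exact p equals brute-force enumeration for all small samples, with and without ties", {
  set.seed(101)
  for (rep in 1:40) {
    n1 <- sample(1:5, 1)
    n2 <- sample(1:5, 1)
    if (rep %% 2 == 0) {
      # ties likely: small integer support
      x <- sample(1:4, n1, replace = TRUE)
      y <- sample(1:4, n2, replace = TRUE)
    } else {
      vals <- sample(1:100, n1 + n2) # tie-free
      x <- vals[seq_len(n1)]
      y <- vals[-seq_len(n1)]
    }
    oracle <- brute_force_mw(x, y)
    got <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(got$u_statistic, oracle$u,
                 info = sprintf("U for x=%s y=%s", toString(x), toString(y)))
    expect_equal(got$p_two_sided, oracle$p, tolerance = 1e-12,
                 info = sprintf("p for x=%s y=%s", toString(x), toString(y)))
  }
})

test_that("tie-free exact p agrees with the reference implementation", {
  set.seed(55)
  for (rep in 1:10) {
    vals <- sample(1:1000, 14)
    x <- vals[1:6]
    y <- vals[7:14]
    got <- mann_whitney_u(x, y, mode = "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
    expect_equal(got$u_statistic, unname(ref$statistic))
  }
})

test_that("the tie-corrected normal approximation agrees with the reference implementation", {
  set.seed(66)
  for (rep in 1:10) {
    x <- sample(0:30, 20, replace = TRUE)
    y <- sample(5:40, 25, replace = TRUE)
    got <- mann_whitney_u(x, y, mode = "normal_approx")
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
    expect_true(got$tie_correction_applied == any(duplicated(c(x, y))) ||
                  !anyDuplicated(c(x, y)))
  }
})

test_that("normal approximation is close to exact for tie-free n1=n2=15 samples", {
  set.seed(77)
  for (rep in 1:10) {
    vals <- sample(seq(0, 1, length.out = 5000), 30)
    x <- vals[1:15]
    y <- vals[16:30]
    pe <- mann_whitney_u(x, y, mode = "exact")$p_two_sided
    pa <- mann_whitney_u(x, y, mode = "normal_approx")$p_two_sided
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("U is antisymmetric in the samples and invariant to location shift", {
  set.seed(88)
  for (rep in 1:10) {
    x <- rnorm(sample(2:8, 1))
    y <- rnorm(sample(2:8, 1))
    a <- mann_whitney_u(x, y)
    b <- mann_whitney_u(y, x)
    expect_equal(a$u_statistic, a$n1 * a$n2 - b$u_statistic)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
    shifted <- mann_whitney_u(x + 17.3, y + 17.3)
    expect_equal(shifted$u_statistic, a$u_statistic)
    expect_equal(shifted$p_two_sided, a$p_two_sided, tolerance = 1e-12)
  }
})

test_that("degenerate and contract cases are handled explicitly", {
  res <- mann_whitney_u(c(4, 4), c(4, 4, 4))
  expect_equal(res$p_two_sided, 1)
  expect_true(res$degenerate)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney_u(1:3, numeric(0)), "non-empty")
  # exact with ties beyond the enumeration gate
  expect_error(mann_whitney_u(rep(1:4, 2), rep(2:6, 2), mode = "exact"),
               "n1 \\+ n2 <= 12")
  # auto picks normal approximation when ties are present
  expect_equal(mann_whitney_u(c(1, 2, 2), c(2, 3, 4))$method, "normal_approx")
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$method, "exact")
})

test_that("p-values lie in (0, 1] and U in [0, n1*n2] over random inputs", {
  set.seed(99)
  for (rep in 1:30) {
    n1 <- sample(1:10, 1)
    n2 <- sample(1:10, 1)
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    for (mode in c("auto", "normal_approx")) {
      res <- mann_whitney_u(x, y, mode = mode)
      expect_gte(res$u_statistic, 0)
      expect_lte(res$u_statistic, n1 * n2)
      expect_gt(res$p_two_sided, 0)
      expect_lte(res$p_two_sided, 1)
    }
  }
})

test_that("shapiro_wilk matches an independently computed reference and guards its domain", {
  # reference W and p computed once with an independent implementation
  # (scipy.stats.shapiro) for this fixed sample
  x <- c(2.1, 3.4, 1.9, 5.6, 4.2, 3.3, 2.8, 4.9, 3.7, 2.5)
  res <- shapiro_wilk(x)
  expect_equal(res$w_statistic, 0.96022430, tolerance = 1e-4)
  expect_equal(res$p_value, 0.78842718, tolerance = 1e-4)
  expect_equal(res$n, 10)

  expect_error(shapiro_wilk(c(1, 2)), "3 <= n <= 5000")
  expect_error(shapiro_wilk(c(4, 4, 4, 4)), "constant sample")
})
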