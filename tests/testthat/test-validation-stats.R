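test_that("Bland-Altman matches hand-computed bias, SD and limits", {
  ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
  expect_equal(ba$bias, -4 / 3, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_low, -4 / 3 - 1.96 * sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high, -4 / 3 + 1.96 * sqrt(13 / 3), tolerance = 1e-12)

  ident <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ident$bias, 0)
  expect_equal(ident$sd_diff, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))

  expect_error(bland_altman(1, 2), "2 pairs")
})

test_that("limits-of-agreement width is exactly 2 * 1.96 * sd", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    ba <- bland_altman(rnorm(n, 5, 10), rnorm(n, 4, 8))
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
    expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  }
})

test_that("paired TOST reports both one-sided statistics at df = n - 1", {
  d <- as.numeric(scale(1:25)) * 10  # mean 0, sd 10, n 25
  ts <- tost_paired(d, bound = 25)
  expect_equal(ts$t_lower, 12.5, tolerance = 1e-12)
  expect_equal(ts$t_upper, -12.5, tolerance = 1e-12)
  expect_equal(ts$df, 24)
  expect_true(ts$equivalent)

  # mean exactly on the bound: t_upper = 0, one-sided p 0.5, not equivalent
  d2 <- as.numeric(scale(1:20)) * 5 + 25
  ts2 <- tost_paired(d2, bound = 25)
  expect_equal(ts2$t_upper, 0, tolerance = 1e-12)
  expect_equal(ts2$p_upper, 0.5, tolerance = 1e-12)
  expect_false(ts2$equivalent)

  # degenerate zero-variance cases
  z_in <- tost_paired(rep(3, 10), bound = 25)
  expect_true(z_in$equivalent)
  expect_equal(z_in$p_equiv, .Machine$double.xmin)
  z_out <- tost_paired(rep(30, 10), bound = 25)
  expect_false(z_out$equivalent)
})

test_that("TOST is symmetric under negation of the differences", {
  set.seed(13)
  for (i in 1:20) {
    d <- rnorm(sample(5:60, 1), rnorm(1, 0, 10), runif(1, 1, 15))
    a <- tost_paired(d, bound = 25)
    b <- tost_paired(-d, bound = 25)
    expect_equal(a$t_lower, -b$t_upper, tolerance = 1e-12)
    expect_equal(a$t_upper, -b$t_lower, tolerance = 1e-12)
    expect_equal(a$p_equiv, b$p_equiv, tolerance = 1e-12)
  }
})

test_that("ICC(2,1) matches the explicit ANOVA-decomposition oracle", {
  m <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  r <- icc_agreement(m)
  expect_equal(r$icc, oracle_icc_a1(m), tolerance = 1e-12)

  # perfect agreement
  ident <- icc_agreement(cbind(1:5, 1:5))
  expect_equal(ident$icc, 1)

  # one rater constant, the other spread: agreement near zero
  set.seed(14)
  m0 <- cbind(rep(5, 20), rnorm(20, 5, 3))
  expect_lt(abs(icc_agreement(m0)$icc), 0.3)

  expect_error(icc_agreement(matrix(2, 4, 2)), "zero total variance")
})

test_that("ICC is shift-invariant and bounded in (-1, 1]", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    m <- cbind(rnorm(n, 100, 20), rnorm(n, 100, 20))
    r <- icc_agreement(m)
    expect_equal(icc_agreement(m + 37.5)$icc, r$icc, tolerance = 1e-9)
    expect_gt(r$icc, -1)
    expect_lte(r$icc, 1)
    expect_true(r$ci_low <= r$icc + 1e-9)
  }
})

test_that("t tests agree with first-principles formulas", {
  set.seed(16)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), 10, 3)
    y <- rnorm(sample(5:40, 1), 11, 4)
    got <- method_t_test(x, y)
    want <- oracle_t_pooled(x, y)
    expect_equal(got$statistic, unname(want["statistic"]), tolerance = 1e-10)
    expect_equal(got$df, unname(want["df"]))
    expect_equal(got$p_value, unname(want["p"]), tolerance = 1e-10)

    z <- rnorm(length(x), 0.5, 2)
    gp <- method_t_test(x, x + z, paired = TRUE)
    wp <- oracle_t_paired(x, x + z)
    expect_equal(gp$statistic, unname(wp["statistic"]), tolerance = 1e-10)
  }
  ident <- method_t_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(method_t_test(c(1, 2, 3), c(2, 3, 4), paired = TRUE),
               "degenerate")
})

test_that("the bundled agreement report carries all four analyses", {
  set.seed(17)
  visual <- rnorm(40, 180, 40)
  automated <- visual + rnorm(40, 5, 12)
  rep <- agreement_report(automated, visual, bound = 25)
  expect_equal(rep$n, 40)
  expect_equal(rep$bland_altman$bias, mean(automated - visual))
  expect_equal(rep$tost$p_equiv,
               oracle_tost(automated - visual, 25), tolerance = 1e-12)
  expect_equal(rep$icc$icc, oracle_icc_a1(cbind(automated, visual)),
               tolerance = 1e-10)
  expect_s3_class(rep, "agreement_report")
})
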