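test_that("dice follows its closed form and symmetry", {
  a <- matrix(FALSE, 4, 4); a[1, 1:4] <- TRUE
  b <- matrix(FALSE, 4, 4); b[1, 3:4] <- TRUE; b[2, 1:2] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)               # identical
  d <- matrix(FALSE, 4, 4); d[4, 4] <- TRUE
  expect_equal(diceCoefficient(a, d), 0)               # disjoint
  expect_equal(diceCoefficient(a, b), 2 * 2 / (4 + 4)) # overlap 2 of 4+4
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  expect_equal(diceCoefficient(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(diceCoefficient(a, matrix(FALSE, 2, 2)), "shapes")
  ## dice == 1 iff identical (nonempty)
  expect_lt(diceCoefficient(a, b), 1)
})

test_that("ICC(2,1) matches the frozen ANOVA oracle", {
  ## rater2 = rater1 + 5 on targets 1..4: MSR = 10/3, MSC = 50, MSE = 0
  ## => ICC = (10/3) / (10/3 + 2*50/4) = 2/17
  tab <- cbind(1:4, (1:4) + 5)
  expect_equal(iccAbsoluteAgreement(tab), 2 / 17, tolerance = 1e-12)
  ## identical columns with between-target variance: perfect agreement
  tab2 <- cbind(c(1, 2, 5, 9), c(1, 2, 5, 9))
  expect_equal(iccAbsoluteAgreement(tab2), 1)
  ## the constant offset strictly lowers absolute agreement
  expect_lt(iccAbsoluteAgreement(tab), 1)
  expect_error(iccAbsoluteAgreement(matrix(1:2, 1, 2)), "targets")
  expect_error(iccAbsoluteAgreement(matrix(0, 4, 2)), "zero total variance")
})

test_that("ICC(2,1) matches an independent two-way ANOVA decomposition", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(4:9, 1); k <- sample(2:4, 1)
    tab <- matrix(rnorm(n * k, 50, 10), n, k) +
      outer(rnorm(n, 0, 5), rep(1, k)) + outer(rep(1, n), rnorm(k, 0, 2))
    df <- data.frame(y = as.numeric(tab),
                     target = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ target + rater, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    expect_equal(iccAbsoluteAgreement(tab), want, tolerance = 1e-10)
    expect_lte(iccAbsoluteAgreement(tab), 1)
  }
})
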