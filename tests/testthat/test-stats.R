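test_that("Cochran-Cox reproduces the published peak-%CDA comparison", {
  ct <- cochran_cox(31.30, 16.91, 33, 11.29, 8.78, 18, alpha = 0.05)
  expect_equal(round(ct$statistic, 2), 5.56)
  expect_equal(round(ct$critical_value, 2), 2.06)
  expect_true(ct$reject)
  expect_lt(ct$p_value, 0.0001)
})

test_that("Cochran-Cox degenerate and invalid inputs", {
  ct <- cochran_cox(10, 2, 15, 10, 3, 20)
  expect_equal(ct$statistic, 0)
  expect_false(ct$reject)
  expect_equal(ct$p_value, 1)
  expect_error(cochran_cox(1, 1, 1, 2, 1, 10), ">= 2")
  expect_error(cochran_cox(1, 0, 10, 2, 1, 10), "> 0")
})

test_that("Cochran-Cox p-value inversion is consistent with the decision rule", {
  set.seed(42)
  for (i in 1:50) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    ct <- cochran_cox(rnorm(1, 0, 3), runif(1, 0.5, 5), n1,
                      rnorm(1, 0, 3), runif(1, 0.5, 5), n2)
    expect_identical(ct$reject, ct$p_value < ct$alpha)
    # the inverted p reproduces |C| as its own critical value
    if (ct$p_value > 1e-12 && ct$p_value < 1 - 1e-12) {
      w1 <- ct$details$w1; w2 <- ct$details$w2
      crit_at_p <- (w1 * qt(1 - ct$p_value / 2, n1 - 1) +
                    w2 * qt(1 - ct$p_value / 2, n2 - 1)) / (w1 + w2)
      expect_equal(crit_at_p, abs(ct$statistic), tolerance = 1e-6)
    }
  }
})

test_that("Cochran-Cox critical value tends to 1.96 for large balanced samples", {
  ct <- cochran_cox(0.1, 1, 10000, 0, 1, 10000)
  expect_lt(abs(ct$critical_value - qnorm(0.975)), 0.01)
})

test_that("Cochran-Cox holds its nominal type-I error under the null", {
  null_rate <- function(n, seed) {
    set.seed(seed)
    x <- matrix(rnorm(n * 10000), n)
    y <- matrix(rnorm(n * 10000), n)
    mx <- colMeans(x); my <- colMeans(y)
    sx <- sqrt(colMeans(x^2) * n / (n - 1) - mx^2 * n / (n - 1))
    sy <- sqrt(colMeans(y^2) * n / (n - 1) - my^2 * n / (n - 1))
    mean(vapply(seq_len(10000), function(i)
      cochran_cox(mx[i], sx[i], n, my[i], sy[i], n)$reject, logical(1)))
  }
  # nominal 5% +- 1% at a sample size where the approximation is accurate
  expect_lt(abs(null_rate(30L, 2024) - 0.05), 0.01)
  # in small samples the weighted critical value is conservative, never
  # anti-conservative: the combined C_kr exceeds the pooled-t critical value
  expect_lt(null_rate(10L, 2024), 0.05 + 0.01)
})

test_that("Mann-Whitney z matches the exact permutation distribution's moments", {
  x <- c(1, 2, 3, 4); y <- c(5, 6, 7)
  mw <- mann_whitney_z(x, y)
  # brute force: all C(7,4) assignments of the pooled values to group 1
  pool <- c(x, y)
  combos <- combn(7, 4)
  U_all <- apply(combos, 2, function(idx)
    sum(rank(pool)[idx]) - 4 * 5 / 2)
  expect_equal(mean(U_all), 4 * 3 / 2)                      # permutation mean
  expect_equal(mw$details$U, 0)                             # all x below all y
  z_oracle <- (0 - mean(U_all)) / (sd(U_all) * sqrt(34 / 35)) # population sd
  # sigma_U^2 (no ties) = n1 n2 (N+1)/12 equals the permutation variance
  expect_equal(mw$statistic, (0 - 6) / sqrt(4 * 3 * 8 / 12))
  expect_equal(mw$statistic, z_oracle, tolerance = 1e-12)
  # exact two-sided p from the enumeration orders the same way
  p_exact <- mean(abs(U_all - 6) >= abs(0 - 6))
  expect_identical(mw$reject, p_exact < 0.06)
})

test_that("Mann-Whitney handles symmetry, ties and the published critical value", {
  s <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney_z(s, s)$statistic, 0)
  expect_equal(mann_whitney_z(s, s, alpha = 0.05)$critical_value,
               qnorm(0.975))
  expect_equal(round(mann_whitney_z(s, s)$critical_value, 2), 1.96)

  # tie-corrected z agrees with the base-R normal approximation (oracle)
  set.seed(31)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(2:8, 9, replace = TRUE)
    mw <- mann_whitney_z(x, y)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mw$details$U, unname(wt$statistic))
    expect_equal(2 * pnorm(-abs(mw$statistic)), wt$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney_z(numeric(0), s), "non-empty")
  # all observations identical: no evidence either way
  expect_equal(mann_whitney_z(rep(2, 4), rep(2, 5))$statistic, 0)
})

test_that("Mann-Whitney z decision agrees with the exact test on small samples", {
  set.seed(77)
  agree <- replicate(1000, {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1, sample(c(0, 2), 1)); y <- rnorm(n2)
    z_dec <- mann_whitney_z(x, y)$reject
    e_dec <- wilcox.test(x, y, exact = TRUE)$p.value < 0.05
    z_dec == e_dec
  })
  expect_gte(mean(agree), 0.95)
})

test_that("chi-square independence reproduces the published bcl-2 analysis", {
  ct <- chi_square_independence(table2_fixture(), alpha = 0.05)
  expect_equal(round(ct$statistic, 2), 2.80)
  expect_equal(ct$df, 3)
  expect_equal(round(ct$critical_value, 2), 7.81)
  expect_equal(round(ct$p_value, 2), 0.42)
  expect_false(ct$reject)
})

test_that("chi-square statistic: oracle, invariances, degenerate tables", {
  # direct O/E double loop on a random table
  set.seed(9)
  tab <- matrix(rpois(12, 8) + 1, 3, 4)
  ct <- chi_square_independence(tab)
  x2 <- 0
  for (i in 1:3) for (j in 1:4) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / sum(tab)
    x2 <- x2 + (tab[i, j] - e)^2 / e
  }
  expect_equal(ct$statistic, x2, tolerance = 1e-12)
  expect_equal(ct$statistic,
               unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic))

  # invariant to row and column permutations
  perm <- chi_square_independence(tab[c(2, 3, 1), c(4, 1, 3, 2)])
  expect_equal(perm$statistic, ct$statistic, tolerance = 1e-12)

  # proportional rows: exact independence
  expect_equal(chi_square_independence(matrix(c(2, 3, 4, 6), 2))$statistic, 0)

  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)),
               "zero margin")
  expect_error(chi_square_independence(matrix(1:3, 3, 1)), "2x2")
})

test_that("coefficient of variation matches all published values to 1 d.p.", {
  expect_equal(round(coefficient_of_variation(10.91, 8.39), 1), 76.9)
  expect_equal(round(coefficient_of_variation(4.27, 5.30), 1), 124.1)
  expect_equal(coefficient_of_variation(10, 0), 0)
  expect_error(coefficient_of_variation(0, 1), "mean = 0")
  expect_error(coefficient_of_variation(10, -1), "sd >= 0")
})

test_that("pearson_r: closed cases and brute-force oracle", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)

  set.seed(14)
  a <- rnorm(20); b <- rnorm(20)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), r_oracle, tolerance = 1e-12)
  expect_equal(pearson_r(a, b), cor(a, b), tolerance = 1e-12)

  expect_error(pearson_r(rep(1, 5), x), "constant")
  expect_error(pearson_r(1:2, 1:2), "length >= 3")
})
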