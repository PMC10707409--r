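#' @keywords internal
.ceus_test <- function(test_name, statistic, critical_value, p_value, alpha,
                       df = NA_real_, reject, details = list()) {
  structure(list(test_name = test_name, statistic = statistic,
                 critical_value = critical_value, p_value = p_value,
                 alpha = alpha, df = df, reject = reject, details = details),
            class = "ceus_test")
}

#' @export
print.ceus_test <- function(x, ...) {
  cat(sprintf("%s\n", x$test_name))
  cat(sprintf("  statistic      = %.4f\n", x$statistic))
  if (!is.na(x$df)) cat(sprintf("  df             = %g\n", x$df))
  cat(sprintf("  critical value = %.4f (alpha = %g, two-sided)\n",
              x$critical_value, x$alpha))
  cat(sprintf("  p-value        = %.4g\n", x$p_value))
  cat(sprintf("  decision       = %s\n",
              if (x$reject) "reject the null" else "do not reject the null"))
  for (nm in names(x$details))
    if (is.numeric(x$details[[nm]]) && length(x$details[[nm]]) == 1L)
      cat(sprintf("  %-14s = %.4f\n", nm, x$details[[nm]]))
  invisible(x)
}

# Cochran-Cox combined critical value at two-sided level `alpha`:
# variance-weighted mix of the per-group Student-t critical values.
# Written via the lower tail so it stays finite for alpha down to ~1e-300.
.cc_critical <- function(alpha, w1, df1, w2, df2) {
  (w1 * (-qt(alpha / 2, df1)) + w2 * (-qt(alpha / 2, df2))) / (w1 + w2)
}

#' Cochran-Cox approximate test for two means with unequal variances
#'
#' The classical approximate solution to the Behrens-Fisher problem from
#' group summaries. The statistic is
#' \deqn{C = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' and the critical value is the variance-weighted combination of the two
#' per-group Student-t critical values,
#' \deqn{C_{kr} = \frac{w_1 t_{1} + w_2 t_{2}}{w_1 + w_2}, \quad
#'       w_i = s_i^2 / n_i,}
#' with \eqn{t_i} the two-sided \eqn{\alpha} critical value on \eqn{n_i - 1}
#' degrees of freedom. The null is rejected when \eqn{|C| > C_{kr}}. The
#' procedure defines a critical value rather than a p-value; the reported
#' p-value is obtained by inverting \eqn{C_{kr}(\alpha) = |C|} in
#' \eqn{\alpha}, which makes `p_value < alpha` equivalent to the rejection
#' rule. (This is not the Welch-Satterthwaite test: no pooled degrees of
#' freedom are formed.)
#'
#' @param mean1,sd1,n1 summary of group 1 (`n1 >= 2`, `sd1 > 0`).
#' @param mean2,sd2,n2 summary of group 2.
#' @param alpha two-sided significance level.
#' @return A `"ceus_test"` with statistic `C`, critical value `C_kr`,
#'   inverted p-value and the rejection decision.
#' @examples
#' # peak %CDA, 33 malignant vs 18 benign adnexal tumours
#' cochran_cox(31.30, 16.91, 33, 11.29, 8.78, 18)
#' @export
cochran_cox <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) .stop_invalid("both group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) .stop_invalid("both SDs must be > 0")
  if (alpha <= 0 || alpha >= 1) .stop_invalid("alpha must be in (0, 1)")
  w1 <- sd1^2 / n1
  w2 <- sd2^2 / n2
  C <- (mean1 - mean2) / sqrt(w1 + w2)
  ckr <- .cc_critical(alpha, w1, n1 - 1, w2, n2 - 1)
  reject <- abs(C) > ckr
  p <- if (C == 0) 1 else {
    f <- function(a) .cc_critical(a, w1, n1 - 1, w2, n2 - 1) - abs(C)
    lo <- 1e-300
    if (f(lo) < 0) 0                       # |C| beyond any computable quantile
    else if (f(1 - 1e-12) > 0) 1
    else uniroot(f, c(lo, 1 - 1e-12), tol = 1e-14)$root
  }
  .ceus_test("Cochran-Cox approximate test (unequal variances)",
             statistic = C, critical_value = ckr, p_value = p, alpha = alpha,
             reject = reject,
             details = list(df1 = n1 - 1, df2 = n2 - 1, w1 = w1, w2 = w2))
}

#' Mann-Whitney U test, normal approximation
#'
#' Rank-sum test for a location difference between two samples. U is computed
#' from midranks; the reported statistic is the large-sample normal deviate
#' \deqn{z = \frac{U - n_1 n_2 / 2}{\sigma_U}} with the tie-corrected
#' standard deviation
#' \deqn{\sigma_U^2 = \frac{n_1 n_2}{12}\Big[(N + 1) -
#'   \frac{\sum_j (t_j^3 - t_j)}{N (N - 1)}\Big],}
#' where \eqn{t_j} are the tie-group sizes and \eqn{N = n_1 + n_2}. No
#' continuity correction is applied. The critical value is the standard
#' normal two-sided quantile (1.96 at `alpha = 0.05`).
#'
#' @param x,y numeric samples (non-empty).
#' @param alpha two-sided significance level.
#' @return A `"ceus_test"`; `details$U` holds the raw U for sample `x`.
#' @export
mann_whitney_z <- function(x, y, alpha = 0.05) {
  if (length(x) == 0L || length(y) == 0L)
    .stop_invalid("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) .stop_invalid("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- if (sigma2 > 0) (U - n1 * n2 / 2) / sqrt(sigma2) else 0
  crit <- qnorm(1 - alpha / 2)
  .ceus_test("Mann-Whitney U test (normal approximation, tie-corrected)",
             statistic = z, critical_value = crit,
             p_value = 2 * pnorm(-abs(z)), alpha = alpha,
             reject = abs(z) > crit, details = list(U = U, n1 = n1, n2 = n2))
}

#' Pearson chi-square test of independence
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with expected counts from the product of
#' the margins; no continuity correction. Degrees of freedom
#' \eqn{(r - 1)(c - 1)}.
#'
#' @param table integer-valued matrix of counts, at least 2x2, with all row
#'   and column sums positive.
#' @param alpha significance level.
#' @return A `"ceus_test"` with the chi-square statistic, its upper-`alpha`
#'   critical value, `df` and p-value.
#' @examples
#' chi_square_independence(table2_fixture())
#' @export
chi_square_independence <- function(table, alpha = 0.05) {
  tab <- as.matrix(table)
  if (!is.numeric(tab) || nrow(tab) < 2L || ncol(tab) < 2L)
    .stop_invalid("`table` must be a numeric matrix of at least 2x2 counts")
  if (anyNA(tab) || any(tab < 0))
    .stop_invalid("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    .stop_invalid("a zero margin makes expected counts undefined")
  E <- outer(rs, cs) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  crit <- qchisq(1 - alpha, df)
  .ceus_test("Pearson chi-square test of independence",
             statistic = x2, critical_value = crit,
             p_value = pchisq(x2, df, lower.tail = FALSE), alpha = alpha,
             df = df, reject = x2 > crit)
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean`. Undefined for a zero mean.
#'
#' @param mean,sd distribution summaries (`mean != 0`, `sd >= 0`); vectors
#'   are handled elementwise.
#' @return Percent CV, same length as the inputs.
#' @examples
#' coefficient_of_variation(10.91, 8.39)  # 76.9 to 1 d.p.
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd < 0))
    .stop_invalid("`mean` and `sd` must be finite with sd >= 0")
  if (any(mean == 0)) .stop_invalid("CV is undefined for mean = 0")
  100 * sd / mean
}

#' Sample Pearson correlation
#'
#' Direct product-moment formula
#' \eqn{r = \sum (x_i - \bar x)(y_i - \bar y) / \sqrt{\sum (x_i - \bar x)^2
#' \sum (y_i - \bar y)^2}}.
#'
#' @param x,y numeric vectors of equal length `>= 3`, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3L || anyNA(x) || anyNA(y))
    .stop_invalid("`x` and `y` must be NA-free numeric vectors of equal length >= 3")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    .stop_invalid("correlation is undefined for a constant input")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  min(max(r, -1), 1)
}
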