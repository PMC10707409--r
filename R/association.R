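#' Dichotomise values at the sample median
#'
#' Standard midpoint sample median; each value is flagged `"at_or_below"`
#' when `value <= median` (the low side is closed) and `"above"` otherwise.
#'
#' @param values non-empty numeric vector without NA.
#' @return List with `median` and `group`, a factor with levels
#'   `"at_or_below"`, `"above"` aligned with `values`.
#' @examples
#' median_split(c(1, 2, 3))
#' @export
median_split <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values))
    .stop_invalid("`values` must be a non-empty numeric vector without NA")
  med <- stats::median(values)
  list(median = med,
       group = factor(ifelse(values <= med, "at_or_below", "above"),
                      levels = c("at_or_below", "above")))
}

#' Cross-tabulate bcl-2 staining intensity against the S median split
#'
#' Dichotomises the cohort's S values at their own median and counts records
#' in each bcl-2 intensity level (0-3) on each side. All four intensity rows
#' are always present (zero rows retained). Records with undefined S
#' (`NA`) or flagged `excluded` are left out; their count is attached as
#' attribute `n_excluded`, the split point as attribute `median`.
#'
#' @param records data frame with columns `s` and `bcl2_intensity` (and
#'   optionally `excluded`), e.g. a [generate_cohort()] cohort merged with
#'   curve features.
#' @return 4x2 integer matrix (rows: intensity 0-3; columns `"<=median"`,
#'   `">median"`) with attributes `median` and `n_excluded`.
#' @seealso [chi_square_independence()], [table2_fixture()]
#' @export
build_bcl2_table <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("s", "bcl2_intensity") %in% names(records)))
    .stop_invalid("`records` must have columns `s` and `bcl2_intensity`")
  drop <- is.na(records$s)
  if (!is.null(records$excluded)) drop <- drop | records$excluded %in% TRUE
  kept <- records[!drop, , drop = FALSE]
  if (nrow(kept) == 0L)
    .stop_invalid("no records with a defined S value")
  if (!all(kept$bcl2_intensity %in% 0:3))
    .stop_invalid("`bcl2_intensity` must be in {0, 1, 2, 3}")
  split <- median_split(kept$s)
  counts <- table(factor(kept$bcl2_intensity, levels = 0:3), split$group)
  out <- matrix(as.integer(counts), nrow = 4,
                dimnames = list(bcl2_intensity = c("0", "1", "2", "3"),
                                s_group = c("<=median", ">median")))
  attr(out, "median") <- split$median
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Correlation between S and a marker expression score
#'
#' Pearson correlation between the integral statistic S and the CD34 or
#' CD105 expression score, with the two-sided t-based significance test on
#' `n - 2` degrees of freedom.
#'
#' @param records data frame with columns `s` and the selected marker.
#' @param marker `"cd34"` or `"cd105"`.
#' @param alpha two-sided significance level.
#' @return A `"ceus_test"`; the t statistic is `statistic`, the correlation
#'   itself is in `details$r`.
#' @export
marker_s_correlation <- function(records, marker = c("cd34", "cd105"),
                                 alpha = 0.05) {
  marker <- match.arg(marker)
  if (!is.data.frame(records) || !all(c("s", marker) %in% names(records)))
    .stop_invalid("`records` must have columns `s` and `", marker, "`")
  keep <- !(is.na(records$s) | is.na(records[[marker]]))
  s <- records$s[keep]
  m <- records[[marker]][keep]
  if (length(s) < 3L)
    .stop_invalid("need at least 3 records with defined S and marker values")
  r <- pearson_r(s, m)
  n <- length(s)
  tstat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  crit <- qt(1 - alpha / 2, n - 2)
  .ceus_test(sprintf("Pearson correlation of S with %s (t test)",
                     toupper(marker)),
             statistic = tstat, critical_value = crit,
             p_value = 2 * pt(-abs(tstat), n - 2), alpha = alpha,
             df = n - 2, reject = abs(tstat) > crit,
             details = list(r = r, n = n))
}
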