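#' Three-band decision rule on the integral statistic S
#'
#' Transparent malignancy triage read off the distribution of S (in units of
#' 10^3 %CDA-seconds): values at or below `low_cut` are called
#' `"likely-benign"`, values strictly above `high_cut` are
#' `"likely-malignant"`, everything between is `"indeterminate"`. Defaults
#' 30 and 90 reflect the reported bands: benign lesions were concentrated
#' below 30 and S above 90 indicated a high probability of malignancy.
#'
#' @param low_cut,high_cut band boundaries, `0 <= low_cut < high_cut`.
#' @return An object of class `"s_band_rule"`.
#' @export
s_band_rule <- function(low_cut = 30, high_cut = 90) {
  if (!is.numeric(low_cut) || !is.numeric(high_cut) ||
      is.na(low_cut) || is.na(high_cut) ||
      low_cut < 0 || low_cut >= high_cut)
    .stop_invalid("need 0 <= low_cut < high_cut")
  structure(list(low_cut = low_cut, high_cut = high_cut),
            class = "s_band_rule")
}

#' @export
print.s_band_rule <- function(x, ...) {
  cat(sprintf("S-band rule: s <= %g likely-benign | %g < s <= %g indeterminate | s > %g likely-malignant\n",
              x$low_cut, x$low_cut, x$high_cut, x$high_cut))
  invisible(x)
}

.s_band_levels <- c("likely-benign", "indeterminate", "likely-malignant")

#' Classify S values into bands
#'
#' Boundary behaviour is exactly as stated by the rule: the low cut is
#' inclusive (`s <= low_cut` is likely-benign), the high cut exclusive
#' (`s > high_cut` is likely-malignant). `NA` values propagate.
#'
#' @param s non-negative S values (units of 10^3 %CDA-seconds); vectorised.
#' @param rule an [s_band_rule()].
#' @return Factor with levels `"likely-benign"`, `"indeterminate"`,
#'   `"likely-malignant"`.
#' @examples
#' classify_s(c(30, 46.9, 90, 90.001))
#' @export
classify_s <- function(s, rule = s_band_rule()) {
  if (!inherits(rule, "s_band_rule"))
    .stop_invalid("`rule` must be an s_band_rule object")
  if (!is.numeric(s) || any(s < 0, na.rm = TRUE))
    .stop_invalid("`s` must be non-negative")
  lab <- ifelse(s <= rule$low_cut, .s_band_levels[1],
                ifelse(s > rule$high_cut, .s_band_levels[3],
                       .s_band_levels[2]))
  factor(lab, levels = .s_band_levels)
}

#' Band frequencies by true label
#'
#' Counts cohort records per S band and malignancy label — the frequency
#' distribution underlying the band rule. Records with undefined S are
#' dropped.
#'
#' @param records data frame with columns `s` and `label`
#'   (`"malignant"`/`"benign"`).
#' @param rule an [s_band_rule()].
#' @return 3x2 integer matrix, rows the bands, columns
#'   `"malignant"`, `"benign"`; sums to the number of records with defined S.
#' @export
band_frequencies <- function(records, rule = s_band_rule()) {
  if (!is.data.frame(records) || !all(c("s", "label") %in% names(records)))
    .stop_invalid("`records` must have columns `s` and `label`")
  kept <- records[!is.na(records$s), , drop = FALSE]
  band <- classify_s(kept$s, rule)
  counts <- table(band, factor(kept$label, levels = c("malignant", "benign")))
  matrix(as.integer(counts), nrow = 3,
         dimnames = list(band = .s_band_levels,
                         label = c("malignant", "benign")))
}
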