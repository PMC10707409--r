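#' Time-intensity curve container
#'
#' A sampled fractional colour-Doppler area series \eqn{F_{\%CDA}(t)} for one
#' exam: strictly increasing times in seconds and values in percent.
#'
#' @param times strictly increasing numeric vector, seconds.
#' @param values %CDA values in `[0, 100]`, same length as `times`.
#' @param exam_id identifier.
#' @return An object of class `"ceus_tic"`.
#' @export
ceus_tic <- function(times, values, exam_id = "exam") {
  if (!is.numeric(times) || !is.numeric(values) ||
      length(times) != length(values) || length(times) < 1L)
    .stop_invalid("`times` and `values` must be numeric of equal positive length")
  if (anyNA(times) || any(diff(times) <= 0))
    .stop_invalid("`times` must be strictly increasing")
  if (anyNA(values) || any(values < -1e-9 | values > 100 + 1e-9))
    .stop_invalid("`values` must lie in [0, 100]")
  structure(list(times = as.numeric(times),
                 values = pmin(pmax(as.numeric(values), 0), 100),
                 exam_id = exam_id),
            class = "ceus_tic")
}

#' @export
print.ceus_tic <- function(x, ...) {
  cat(sprintf("%%CDA time-intensity curve '%s': %d samples, t in [%g, %g] s, peak %.2f%%\n",
              x$exam_id, length(x$times), x$times[1],
              x$times[length(x$times)], max(x$values)))
  invisible(x)
}

#' @export
plot.ceus_tic <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time [s]",
       ylab = "%CDA", main = x$exam_id, ylim = c(0, max(100, x$values)), ...)
  invisible(x)
}

#' Integral perfusion statistic S
#'
#' Computes \deqn{S = \int_0^{T^*} F_{\%CDA}(t)\, dt} by the trapezoid rule
#' (exact for piecewise-linear curves sampled at their breakpoints), with
#' linear interpolation to `t_star` when it falls between samples, and
#' reports it in units of \eqn{10^3} %CDA-seconds (the raw integral divided
#' by 1000). `t_star` is the upper integration limit shared by all curves
#' under comparison — see [choose_t_star()]. No extrapolation: `t_star`
#' beyond the sampled support is an error.
#'
#' @param curve a [ceus_tic()] curve.
#' @param t_star upper integration limit, seconds; defaults to the curve's
#'   last sample.
#' @return Non-negative scalar, S in units of 10^3 %CDA-seconds.
#' @examples
#' tic <- ceus_tic(times = seq(0, 100, 10), values = rep(50, 11))
#' integral_s(tic)  # 50% over 100 s: 5000 / 1000 = 5
#' @export
integral_s <- function(curve, t_star = NULL) {
  if (!inherits(curve, "ceus_tic"))
    .stop_invalid("`curve` must be a ceus_tic object")
  tt <- curve$times; vv <- curve$values
  if (is.null(t_star)) t_star <- tt[length(tt)]
  if (t_star > tt[length(tt)] + 1e-12)
    .stop_invalid("t_star is beyond the sampled support of the curve")
  keep <- tt <= t_star
  if (sum(keep) < 2L)
    .stop_invalid("need at least two samples at or below t_star")
  t2 <- tt[keep]; v2 <- vv[keep]
  if (t2[length(t2)] < t_star) {
    t2 <- c(t2, t_star)
    v2 <- c(v2, approx(tt, vv, xout = t_star)$y)
  }
  sum(diff(t2) * (v2[-1] + v2[-length(v2)]) / 2) / 1000
}

#' Common upper integration limit across a cohort
#'
#' The integral statistic S is only comparable across exams when all curves
#' are integrated to the same limit; the largest such limit available without
#' extrapolating any exam is the minimum of the curves' last sample times.
#'
#' @param curves non-empty list of [ceus_tic()] curves.
#' @return Scalar `t_star`, seconds.
#' @export
choose_t_star <- function(curves) {
  if (!is.list(curves) || length(curves) == 0L)
    .stop_invalid("`curves` must be a non-empty list of ceus_tic objects")
  min(vapply(curves, function(cu) {
    if (!inherits(cu, "ceus_tic")) .stop_invalid("all elements must be ceus_tic")
    cu$times[length(cu$times)]
  }, numeric(1)))
}

#' Extract enhancement-curve features
#'
#' Computes the standard descriptive parameter set of a wash-in/wash-out
#' %CDA curve:
#' \describe{
#'   \item{`y_start`}{baseline %CDA, the mean over the pre-contrast window
#'     `[0, t_kts]` (equals the plateau value on noise-free curves).}
#'   \item{`t_max`, `y_max`}{time and value of the curve maximum (first
#'     sample on ties).}
#'   \item{`delta`}{relative enhancement `y_max / y_start`; `NA` when the
#'     baseline is zero (never infinity).}
#'   \item{`t_end`, `y_end`}{last sample.}
#'   \item{`t_sp`}{wash-out duration `t_end - t_max`.}
#'   \item{`d`}{falling speed, the wash-out chord slope
#'     `(y_end - y_max) / t_sp` in %/s (non-positive when the curve ends at
#'     or below its peak); `NA` when `t_sp = 0` with `y_end != y_max`.}
#'   \item{`s`}{the integral statistic [integral_s()] over `[0, t_star]`.}
#' }
#'
#' @param curve a [ceus_tic()] curve.
#' @param t_kts contrast-administration time, seconds; must lie within the
#'   sampled support.
#' @param t_star upper integration limit for `s`; defaults to the curve's
#'   last sample time (use [choose_t_star()] for cohort work).
#' @param smooth_window optional odd integer: moving-average window applied
#'   to the values before locating the maximum (the integral always uses the
#'   raw samples). Default `NULL`, no smoothing.
#' @return An object of class `"ceus_features"` — a named list with the
#'   fields above plus `t_kts`, `t_star`, `exam_id`.
#' @export
extract_features <- function(curve, t_kts, t_star = NULL,
                             smooth_window = NULL) {
  if (!inherits(curve, "ceus_tic"))
    .stop_invalid("`curve` must be a ceus_tic object")
  tt <- curve$times; vv <- curve$values
  if (!is.numeric(t_kts) || length(t_kts) != 1L ||
      t_kts < tt[1] || t_kts > tt[length(tt)])
    .stop_invalid("`t_kts` must lie within the curve's time support")
  if (is.null(t_star)) t_star <- tt[length(tt)]

  v_peak <- vv
  if (!is.null(smooth_window)) {
    w <- as.integer(smooth_window)
    if (w < 1L || w %% 2L == 0L)
      .stop_invalid("`smooth_window` must be a positive odd integer")
    if (w > 1L) {
      sm <- stats::filter(vv, rep(1 / w, w), sides = 2)
      v_peak <- ifelse(is.na(sm), vv, as.numeric(sm))
    }
  }

  y_start <- mean(vv[tt <= t_kts])
  i_max <- which.max(v_peak)            # first index on ties
  t_max <- tt[i_max]; y_max <- vv[i_max]
  n <- length(tt)
  t_end <- tt[n]; y_end <- vv[n]
  t_sp <- t_end - t_max
  d <- if (t_sp > 0) (y_end - y_max) / t_sp
       else if (y_end == y_max) 0 else NA_real_
  delta <- if (y_start > 0) y_max / y_start else NA_real_
  s <- integral_s(curve, t_star)
  structure(list(y_start = y_start, t_kts = t_kts, t_max = t_max,
                 y_max = y_max, delta = delta, t_end = t_end, y_end = y_end,
                 t_sp = t_sp, d = d, s = s, t_star = t_star,
                 exam_id = curve$exam_id),
            class = "ceus_features")
}

#' @export
print.ceus_features <- function(x, ...) {
  cat(sprintf("Enhancement-curve features for '%s'\n", x$exam_id))
  cat(sprintf("  y_start = %.3f %%   y_max = %.3f %% at t_max = %g s\n",
              x$y_start, x$y_max, x$t_max))
  cat(sprintf("  delta   = %s        y_end = %.3f %% at t_end = %g s\n",
              if (is.na(x$delta)) "NA" else sprintf("%.3f", x$delta),
              x$y_end, x$t_end))
  cat(sprintf("  t_sp    = %g s      D = %s %%/s\n", x$t_sp,
              if (is.na(x$d)) "NA" else sprintf("%.4f", x$d)))
  cat(sprintf("  S       = %.4f (x10^3 %%CDA*s, T* = %g s)\n", x$s, x$t_star))
  invisible(x)
}

#' @export
as.data.frame.ceus_features <- function(x, ...) {
  data.frame(exam_id = x$exam_id, y_start = x$y_start, t_kts = x$t_kts,
             t_max = x$t_max, y_max = x$y_max, delta = x$delta,
             t_end = x$t_end, y_end = x$y_end, t_sp = x$t_sp, d = x$d,
             s = x$s, t_star = x$t_star, stringsAsFactors = FALSE)
}

#' Feature table for a set of curves
#'
#' Applies [extract_features()] to every curve using one shared integration
#' limit (by default [choose_t_star()] of the set, so S is comparable across
#' exams).
#'
#' @param curves list of [ceus_tic()] curves.
#' @param t_kts contrast-administration time, seconds.
#' @param t_star shared upper integration limit; default `choose_t_star(curves)`.
#' @param ... passed to [extract_features()].
#' @return Data frame, one row per curve.
#' @export
cohort_features <- function(curves, t_kts, t_star = NULL, ...) {
  if (is.null(t_star)) t_star <- choose_t_star(curves)
  do.call(rbind, lapply(curves, function(cu)
    as.data.frame(extract_features(cu, t_kts = t_kts, t_star = t_star, ...))))
}
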