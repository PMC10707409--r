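#' Kinetic parameters of a three-phase enhancement curve
#'
#' Bundles the parameters of an idealised contrast-enhancement time-intensity
#' curve: a pre-contrast plateau at `y_start` until the contrast-administration
#' time `t_kts`, a rapid monotone rise to the peak `y_max` at `t_max`, and a
#' slower monotone decay to `y_end` at the end of acquisition `t_end`. All
#' intensity values are fractional colour-Doppler areas (%CDA) in percent.
#'
#' @param y_start baseline %CDA before contrast arrival, in `[0, 100]`.
#' @param y_max peak %CDA, `y_max >= y_start`.
#' @param t_kts contrast-administration time in seconds (end of baseline).
#' @param t_max time of the peak, seconds; `t_kts < t_max < t_end`.
#' @param t_end end of acquisition, seconds.
#' @param y_end final %CDA, in `[0, 100]`.
#' @param noise_sd standard deviation (percentage points) of additive Gaussian
#'   measurement noise applied by [make_kinetic_curve()]; `0` for noise-free.
#' @return An object of class `"kinetic_params"`.
#' @seealso [make_kinetic_curve()], [render_frames()]
#' @examples
#' kinetic_params(y_start = 4, y_max = 30, t_kts = 10, t_max = 30,
#'                t_end = 120, y_end = 6)
#' @export
kinetic_params <- function(y_start, y_max, t_kts, t_max, t_end, y_end,
                           noise_sd = 0) {
  for (v in list(y_start, y_max, t_kts, t_max, t_end, y_end, noise_sd))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      .stop_invalid("all kinetic parameters must be finite numeric scalars")
  if (y_start < 0 || y_start > y_max || y_max > 100)
    .stop_invalid("need 0 <= y_start <= y_max <= 100")
  if (y_end < 0 || y_end > 100)
    .stop_invalid("need 0 <= y_end <= 100")
  if (!(t_kts < t_max && t_max < t_end))
    .stop_invalid("need t_kts < t_max < t_end")
  if (t_kts < 0)
    .stop_invalid("t_kts must be non-negative")
  if (noise_sd < 0)
    .stop_invalid("noise_sd must be >= 0")
  structure(list(y_start = y_start, y_max = y_max, t_kts = t_kts,
                 t_max = t_max, t_end = t_end, y_end = y_end,
                 noise_sd = noise_sd),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Three-phase enhancement kinetics\n")
  cat(sprintf("  baseline  : %.2f %%CDA on [0, %g] s\n", x$y_start, x$t_kts))
  cat(sprintf("  peak      : %.2f %%CDA at t = %g s\n", x$y_max, x$t_max))
  cat(sprintf("  end       : %.2f %%CDA at t = %g s\n", x$y_end, x$t_end))
  cat(sprintf("  noise sd  : %g\n", x$noise_sd))
  invisible(x)
}

# normalised smooth monotone ramp on [0, 1]: g(0) = 0, g(1) = 1
.logistic_ramp <- function(u, k = 8) {
  (plogis(k * (u - 0.5)) - plogis(-k / 2)) / (plogis(k / 2) - plogis(-k / 2))
}

#' Synthesize a %CDA time-intensity curve
#'
#' Evaluates the three-phase enhancement model of a [kinetic_params()] object
#' on a sampling grid: constant `y_start` on `[0, t_kts]`, a monotone
#' non-decreasing rise to `y_max` at `t_max`, and a monotone non-increasing
#' decay to `y_end` at `t_end`. The rise must be at least as steep (on
#' average) as the decay — the wash-in is the fast phase. With
#' `noise_sd > 0`, i.i.d. Gaussian noise is added and the result clipped to
#' `[0, 100]`; noise is drawn from the current RNG state.
#'
#' @param params a [kinetic_params()] object.
#' @param times strictly increasing sampling times, seconds, within
#'   `[0, t_end]`.
#' @param shape `"linear"` (piecewise-linear segments, the default: exact
#'   under trapezoidal integration) or `"logistic"` (smooth ramps).
#' @return Numeric vector of %CDA values, one per element of `times`.
#' @examples
#' p <- kinetic_params(4, 30, t_kts = 10, t_max = 30, t_end = 120, y_end = 6)
#' y <- make_kinetic_curve(p, times = 0:120)
#' y[21]  # t = 20 s, midpoint of the linear rise: 17
#' @export
make_kinetic_curve <- function(params, times, shape = c("linear", "logistic")) {
  if (!inherits(params, "kinetic_params"))
    .stop_invalid("`params` must be a kinetic_params object")
  shape <- match.arg(shape)
  if (!is.numeric(times) || length(times) < 1L || anyNA(times))
    .stop_invalid("`times` must be a non-empty numeric vector")
  if (any(diff(times) <= 0))
    .stop_invalid("`times` must be strictly increasing")
  if (times[1] < 0 || times[length(times)] > params$t_end)
    .stop_invalid("`times` must lie within [0, t_end]")

  rise_slope <- (params$y_max - params$y_start) / (params$t_max - params$t_kts)
  decay_slope <- (params$y_max - params$y_end) / (params$t_end - params$t_max)
  if (decay_slope > rise_slope)
    .stop_invalid("decay steeper than rise: not a wash-in/wash-out curve ",
                  "(need (y_max - y_end)/(t_end - t_max) <= ",
                  "(y_max - y_start)/(t_max - t_kts))")

  y <- numeric(length(times))
  base <- times <= params$t_kts
  rise <- times > params$t_kts & times <= params$t_max
  fall <- times > params$t_max
  y[base] <- params$y_start
  u_r <- (times[rise] - params$t_kts) / (params$t_max - params$t_kts)
  u_f <- (times[fall] - params$t_max) / (params$t_end - params$t_max)
  if (shape == "linear") {
    y[rise] <- params$y_start + (params$y_max - params$y_start) * u_r
    y[fall] <- params$y_max + (params$y_end - params$y_max) * u_f
  } else {
    y[rise] <- params$y_start +
      (params$y_max - params$y_start) * .logistic_ramp(u_r)
    y[fall] <- params$y_max +
      (params$y_end - params$y_max) * .logistic_ramp(u_f)
  }
  if (params$noise_sd > 0) {
    y <- y + rnorm(length(y), 0, params$noise_sd)
    y <- pmin(pmax(y, 0), 100)
  }
  y
}

#' Default elliptical region of interest
#'
#' A centred ellipse covering roughly 45% of the image — a stand-in for the
#' operator-drawn outline of the solid part of the tumour cross-section.
#'
#' @param image_shape integer vector `c(rows, cols)`.
#' @return Logical matrix of the given shape.
#' @export
default_roi <- function(image_shape = c(64L, 64L)) {
  h <- image_shape[1]; w <- image_shape[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- 0.38 * h; rx <- 0.38 * w
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1
}

#' Render a %CDA curve as a synthetic colour-Doppler frame sequence
#'
#' Produces one RGB frame per time point: a greyscale speckle background with
#' vessel-like coloured blobs inside the region of interest. In frame `i` the
#' fraction of ROI pixels carrying colour matches `curve[i]` up to one-pixel
#' quantisation (`|rendered - requested| <= 100 / sum(roi)` percentage
#' points). Colour pixels grow outward from `n_blobs` seed points, so they
#' stay spatially clustered; blob placement and background speckle are driven
#' by `seed`.
#'
#' @param curve %CDA values in `[0, 100]`, one per time point.
#' @param times strictly increasing times, seconds.
#' @param image_shape frame dimensions `c(rows, cols)`.
#' @param roi logical ROI mask of shape `image_shape`; defaults to
#'   [default_roi()]. Must contain at least one pixel.
#' @param n_blobs number of vessel-like colour foci.
#' @param seed integer seed for blob placement and speckle; `NULL` uses the
#'   current RNG state.
#' @return An object of class `"ceus_frames"`: list with `times`, `frames`
#'   (list of `rows x cols x 3` arrays, values 0-255), `roi_mask`, `seed`.
#' @seealso [extract_curve()] for the inverse operation.
#' @export
render_frames <- function(curve, times, image_shape = c(64L, 64L), roi = NULL,
                          n_blobs = 3L, seed = NULL) {
  if (!is.numeric(curve) || anyNA(curve) || any(curve < 0 | curve > 100))
    .stop_invalid("`curve` values must be in [0, 100]")
  if (length(curve) != length(times) || any(diff(times) <= 0))
    .stop_invalid("`times` must be strictly increasing and match `curve`")
  if (is.null(roi)) roi <- default_roi(image_shape)
  if (!is.logical(roi) || !identical(dim(roi), as.integer(image_shape)))
    .stop_invalid("`roi` must be a logical matrix of shape `image_shape`")
  n_roi <- sum(roi)
  if (n_roi == 0L) .stop_invalid("ROI is empty")

  .with_seed(seed, {
    h <- image_shape[1]; w <- image_shape[2]
    grey <- matrix(round(runif(h * w, 40, 140)), h, w)
    roi_idx <- which(roi)
    rows <- ((roi_idx - 1) %% h) + 1
    cols <- ((roi_idx - 1) %/% h) + 1
    centres <- sample(seq_along(roi_idx), min(n_blobs, n_roi))
    # distance to the nearest blob centre + jitter: colour fills outward from
    # the centres, giving contiguous vessel-like patches at any fill level
    d <- rep(Inf, n_roi)
    for (ci in centres) {
      d <- pmin(d, sqrt((rows - rows[ci])^2 + (cols - cols[ci])^2))
    }
    fill_order <- order(d + runif(n_roi, 0, 0.25))
    frames <- vector("list", length(curve))
    for (i in seq_along(curve)) {
      fr <- array(0, dim = c(h, w, 3L))
      fr[, , 1] <- grey; fr[, , 2] <- grey; fr[, , 3] <- grey
      n_col <- round(curve[i] / 100 * n_roi)
      if (n_col > 0L) {
        sel <- roi_idx[fill_order[seq_len(n_col)]]
        fr[sel] <- 220                     # R channel
        fr[sel + h * w] <- 30              # G channel
        fr[sel + 2 * h * w] <- 30          # B channel
      }
      frames[[i]] <- fr
    }
    structure(list(times = times, frames = frames, roi_mask = roi,
                   seed = seed),
              class = "ceus_frames")
  })
}

#' @export
print.ceus_frames <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Synthetic CEUS frame sequence: %d frames of %dx%d, %d ROI pixels, t in [%g, %g] s\n",
              length(x$frames), d[1], d[2], sum(x$roi_mask),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Cohort specification for the synthetic-exam generator
#'
#' Describes a two-group (malignant / benign) cohort by its group sizes,
#' per-group moments of the kinetic summaries (`y_start`, `y_max` in %CDA and
#' the integral statistic `s` in units of 10^3 %CDA-seconds), a log-normal
#' model for the CD34 and CD105 expression scores, and category probabilities
#' for bcl-2 staining intensity (ordinal 0-3). Defaults reproduce the
#' published group-level summary of 33 malignant and 18 benign adnexal
#' tumours; markers are drawn independently of the kinetics, encoding the
#' published null association between perfusion and immunohistochemistry.
#'
#' @param n_malignant,n_benign group sizes (non-negative integers).
#' @param kinetics per-group list of `c(mean, sd)` for `y_start`, `y_max`
#'   and `s`.
#' @param markers per-group `c(meanlog, sdlog)` for `cd34` and `cd105`, plus
#'   `bcl2_prob`, four probabilities for intensities 0-3 (must sum to 1).
#' @param seed integer seed making the generated cohort reproducible.
#' @return An object of class `"cohort_spec"`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_malignant = 33L, n_benign = 18L,
                        kinetics = list(
                          malignant = list(y_start = c(mean = 10.91, sd = 8.39),
                                           y_max   = c(mean = 31.30, sd = 16.91),
                                           s       = c(mean = 80.5,  sd = 50.6)),
                          benign    = list(y_start = c(mean = 4.27,  sd = 5.30),
                                           y_max   = c(mean = 11.29, sd = 8.78),
                                           s       = c(mean = 25.00, sd = 22.67))),
                        markers = list(
                          malignant = list(cd34  = c(meanlog = 4.0, sdlog = 0.5),
                                           cd105 = c(meanlog = 3.0, sdlog = 0.6)),
                          benign    = list(cd34  = c(meanlog = 3.4, sdlog = 0.5),
                                           cd105 = c(meanlog = 2.4, sdlog = 0.6)),
                          bcl2_prob = c(17, 11, 8, 5) / 41),
                        seed = 1L) {
  if (n_malignant < 0 || n_benign < 0)
    .stop_invalid("group sizes must be non-negative")
  for (g in c("malignant", "benign"))
    for (p in c("y_start", "y_max", "s")) {
      ms <- kinetics[[g]][[p]]
      if (is.null(ms) || length(ms) != 2L || anyNA(ms) || ms[2] < 0)
        .stop_invalid("kinetics$", g, "$", p, " must be c(mean, sd) with sd >= 0")
    }
  pb <- markers$bcl2_prob
  if (length(pb) != 4L || any(pb < 0) || abs(sum(pb) - 1) > 1e-9)
    .stop_invalid("bcl2_prob must be 4 non-negative probabilities summing to 1")
  structure(list(n_malignant = as.integer(n_malignant),
                 n_benign = as.integer(n_benign),
                 kinetics = kinetics, markers = markers,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort of exam records
#'
#' Draws one record per patient: kinetic summaries (`y_start`, `y_max`, `s`)
#' from per-group distributions whose mean and SD equal the specification's
#' moments, and an immunohistochemistry panel (`cd34`, `cd105`,
#' `bcl2_intensity`) drawn independently of the kinetics. The kinetic
#' marginals use a truncated normal solved so that its *truncated* moments
#' hit the targets (`y_start`, `y_max` on \eqn{[0, 100]}, `s` on
#' \eqn{[0, \infty)}); where the target coefficient of variation exceeds what
#' a truncated normal can attain on the half-line (CV = 1), a moment-matched
#' gamma is used instead.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame of class `"ceus_cohort"` with columns `patient_id`,
#'   `label` (`"malignant"`/`"benign"`), `y_start`, `y_max`, `s`, `cd34`,
#'   `cd105`, `bcl2_intensity` (integer 0-3) and `excluded` (logical, all
#'   `FALSE`: a hook for curve-acquisition failures, no rule is imposed).
#'   Two calls with the same spec (including seed) are identical.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 42))
#' table(cohort$label)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    .stop_invalid("`spec` must be a cohort_spec object")
  .with_seed(spec$seed, {
    draw_group <- function(g, n) {
      if (n == 0L) return(NULL)
      k <- spec$kinetics[[g]]
      mk <- spec$markers[[g]]
      data.frame(
        label = rep(g, n),
        y_start = .draw_moments(n, k$y_start[1], k$y_start[2], 0, 100),
        y_max = .draw_moments(n, k$y_max[1], k$y_max[2], 0, 100),
        s = .draw_moments(n, k$s[1], k$s[2], 0, Inf),
        cd34 = rlnorm(n, mk$cd34[1], mk$cd34[2]),
        cd105 = rlnorm(n, mk$cd105[1], mk$cd105[2]),
        bcl2_intensity = sample(0:3, n, replace = TRUE,
                                prob = spec$markers$bcl2_prob),
        stringsAsFactors = FALSE)
    }
    out <- rbind(draw_group("malignant", spec$n_malignant),
                 draw_group("benign", spec$n_benign))
    if (is.null(out))
      out <- data.frame(label = character(0), y_start = numeric(0),
                        y_max = numeric(0), s = numeric(0),
                        cd34 = numeric(0), cd105 = numeric(0),
                        bcl2_intensity = integer(0))
    out <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(out)) + 0L)[seq_len(nrow(out))],
                 out)
    out$excluded <- logical(nrow(out))
    rownames(out) <- NULL
    structure(out, spec = spec, class = c("ceus_cohort", "data.frame"))
  })
}

#' Realise an exam record as full enhancement kinetics
#'
#' Solves for the time coordinates of a three-phase curve that reproduces a
#' record's drawn summaries: baseline `min(y_start, y_max)`, peak `y_max`,
#' and — decisive — a trapezoidal integral over `[0, t_end]` equal to
#' `1000 * s` %CDA-seconds. The contrast-administration time and rise
#' duration are fixed (wash-in is fast); the wash-out duration `t_end - t_max`
#' and the final value `y_end` are solved so the integral is hit exactly on
#' the sampling grid. Because `s` is specified in units of 10^3 %CDA-seconds
#' while %CDA is capped at 100, realised acquisitions typically span
#' thousands of seconds.
#'
#' @param y_start,y_max,s kinetic summaries, e.g. one row of a
#'   [generate_cohort()] cohort.
#' @param t_kts contrast-administration time, seconds (integer).
#' @param rise_s wash-in duration, seconds (integer); shrunk automatically if
#'   the target `s` is too small to allow a slower wash-out.
#' @param frame_rate frames per second of the sampling grid (integer, so the
#'   grid contains the segment breakpoints and the trapezoid rule is exact).
#' @param noise_sd measurement-noise SD passed to the kinetic parameters.
#' @return List with `params` ([kinetic_params()]) and `times` (the sampling
#'   grid); `make_kinetic_curve(params, times)` integrates to `1000 * s`.
#' @export
kinetics_from_record <- function(y_start, y_max, s, t_kts = 10L, rise_s = 20L,
                                 frame_rate = 1L, noise_sd = 0) {
  if (any(!is.finite(c(y_start, y_max, s))) || s < 0 || y_max <= 0)
    .stop_invalid("record summaries must be finite with s >= 0, y_max > 0")
  ys <- min(y_start, y_max)
  # a drawn baseline at (or nearly at) the peak leaves no wash-in phase;
  # realise such records with the baseline at 80% of the peak (the record
  # keeps its drawn values, only the rendered curve is affected)
  if (y_max - ys < 0.05 * y_max) ys <- 0.8 * y_max
  s_raw <- 1000 * s
  y_end_max <- min(100, y_max)
  r <- as.integer(rise_s)
  d <- NA
  repeat {
    a0 <- ys * t_kts
    a_rise <- r * (ys + y_max) / 2
    rem <- s_raw - a0 - a_rise
    if (rem > 0) {
      # integer wash-out duration d must keep y_end = 2*rem/d - y_max inside
      # [0, y_end_max] and the wash-out chord slope below the wash-in slope:
      # k d^2 - 2 y_max d + 2 rem >= 0 with k = (y_max - ys)/r (larger root)
      k <- (y_max - ys) / r
      disc <- 4 * y_max^2 - 8 * k * rem
      d_slope <- if (disc > 0) (2 * y_max + sqrt(disc)) / (2 * k) else 0
      d_lo <- max(r + 1, ceiling(2 * rem / (y_max + y_end_max)),
                  ceiling(d_slope))
      d_hi <- floor(2 * rem / y_max)
      if (d_lo <= d_hi) {
        # aim for y_end near the baseline, within the feasible window
        d <- min(max(round(2 * rem / (y_max + ys)), d_lo), d_hi)
        break
      }
    }
    if (r <= 1L)
      .stop_invalid("target s too small to realise a three-phase curve ",
                    "with this baseline")
    r <- max(1L, r %/% 2L)
  }
  t_max <- t_kts + r
  t_end <- t_max + d
  y_end <- min(max(2 * rem / d - y_max, 0), y_end_max)
  params <- kinetic_params(ys, y_max, t_kts, t_max, t_end, y_end, noise_sd)
  list(params = params, times = seq(0, t_end, by = 1 / as.integer(frame_rate)))
}

#' Published bcl-2 x S-median contingency table
#'
#' The printed cross-tabulation of bcl-2 staining intensity (rows, ordinal
#' 0-3) against the S statistic dichotomised at its cohort median (columns),
#' for the 41 patients with evaluable curves. Used as a fixed reference input
#' for the chi-square independence analysis.
#'
#' @return A 4x2 integer matrix with dimnames `bcl2_intensity` (0-3) and
#'   `s_group` (`"<=median"`, `">median"`). Grand total 41.
#' @examples
#' chi_square_independence(table2_fixture())
#' @export
table2_fixture <- function() {
  matrix(c(7L, 10L,
           5L, 6L,
           6L, 2L,
           2L, 3L),
         nrow = 4, byrow = TRUE,
         dimnames = list(bcl2_intensity = c("0", "1", "2", "3"),
                         s_group = c("<=median", ">median")))
}
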