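# Shared fixtures built in code.

# canonical hand-checkable kinetics: linear rise 4 -> 30 over [10, 30],
# linear decay to 6 at 120
test_params <- function(noise_sd = 0) {
  kinetic_params(y_start = 4, y_max = 30, t_kts = 10, t_max = 30,
                 t_end = 120, y_end = 6, noise_sd = noise_sd)
}

test_tic <- function(times = 0:120) {
  ceus_tic(times, make_kinetic_curve(test_params(), times))
}

# a frame with an explicit set of coloured pixels (linear indices into h x w)
solid_frame <- function(h, w, colour_idx = integer(0), grey = 100) {
  fr <- array(grey, dim = c(h, w, 3))
  if (length(colour_idx)) {
    fr[colour_idx] <- 220
    fr[colour_idx + h * w] <- 30
    fr[colour_idx + 2 * h * w] <- 30
  }
  fr
}

frames_from_masks <- function(masks, roi, times = seq_along(masks) - 1) {
  h <- nrow(roi); w <- ncol(roi)
  structure(list(times = times,
                 frames = lapply(masks, function(m) solid_frame(h, w, which(m))),
                 roi_mask = roi, seed = NULL),
            class = "ceus_frames")
}

# closed-form area of a piecewise-linear curve defined by breakpoints
segment_area <- function(t_break, y_break) {
  sum(diff(t_break) * (head(y_break, -1) + tail(y_break, -1)) / 2)
}

# published group summaries (means, SDs): malignant / benign
table1_moments <- function() {
  list(malignant = list(y_start = c(10.91, 8.39), y_max = c(31.30, 16.91),
                        s = c(80.5, 50.6)),
       benign = list(y_start = c(4.27, 5.30), y_max = c(11.29, 8.78),
                     s = c(25.00, 22.67)))
}
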