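#' Segment colour-Doppler overlay pixels in one frame
#'
#' Marks a pixel as carrying colour (flow) signal when its channel spread —
#' maximum minus minimum across R, G, B — exceeds a chroma threshold.
#' Greyscale background has zero spread regardless of brightness, so this
#' separates the colour overlay from speckle without a scanner colour map.
#'
#' @param frame numeric array `rows x cols x 3` on a 0-255 scale.
#' @param chroma_threshold minimum channel spread for a colour pixel
#'   (default 10).
#' @return Logical matrix: `TRUE` where the pixel carries colour.
#' @export
colour_mask <- function(frame, chroma_threshold = 10) {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    .stop_invalid("`frame` must be an array with three colour channels")
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  (pmax(r, g, b) - pmin(r, g, b)) > chroma_threshold
}

#' Extract the %CDA time-intensity curve from a frame sequence
#'
#' For each frame, the fractional colour-Doppler area is the percentage of
#' region-of-interest pixels whose [colour_mask()] is set:
#' `100 * |mask & roi| / |roi|`. The ROI is fixed across frames (the probe
#' holds one tumour cross-section throughout the exam).
#'
#' @param seq a `"ceus_frames"` sequence, e.g. from [render_frames()] or
#'   [read_frames()].
#' @param chroma_threshold passed to [colour_mask()].
#' @param exam_id identifier attached to the returned curve.
#' @return A [ceus_tic()] time-intensity curve.
#' @export
extract_curve <- function(seq, chroma_threshold = 10, exam_id = "exam") {
  if (!inherits(seq, "ceus_frames"))
    .stop_invalid("`seq` must be a ceus_frames object")
  roi <- seq$roi_mask
  n_roi <- sum(roi)
  if (n_roi == 0L) .stop_invalid("ROI is empty")
  values <- vapply(seq$frames, function(f) {
    100 * sum(colour_mask(f, chroma_threshold) & roi) / n_roi
  }, numeric(1))
  ceus_tic(seq$times, values, exam_id = exam_id)
}
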