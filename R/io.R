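# Plain-text interchange: curve CSV, cohort CSV, ASCII-PPM frame directories.

#' Write / read a time-intensity curve as CSV
#'
#' Two-column CSV with header `time_s,cda_percent`.
#'
#' @param curve a [ceus_tic()] curve.
#' @param path file path.
#' @return `write_curve` returns `path` invisibly; `read_curve` a
#'   [ceus_tic()].
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "ceus_tic")) .stop_invalid("`curve` must be a ceus_tic")
  utils::write.csv(data.frame(time_s = curve$times,
                              cda_percent = curve$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @param exam_id identifier for the curve read from `path`.
#' @export
read_curve <- function(path, exam_id = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "cda_percent") %in% names(df)))
    .stop_invalid("curve CSV must have columns time_s, cda_percent")
  ceus_tic(df$time_s, df$cda_percent, exam_id = exam_id)
}

#' Write / read a synthetic cohort as CSV
#'
#' Columns `patient_id,label,y_start,y_max,s,cd34,cd105,bcl2_intensity`.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("patient_id", "label", "y_start", "y_max", "s",
            "cd34", "cd105", "bcl2_intensity")
  if (!all(cols %in% names(cohort)))
    .stop_invalid("`cohort` is missing required columns")
  utils::write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(df$label %in% c("malignant", "benign")))
    .stop_invalid("cohort labels must be 'malignant' or 'benign'")
  if (!all(df$bcl2_intensity %in% 0:3))
    .stop_invalid("bcl2_intensity must be in {0, 1, 2, 3}")
  df$excluded <- logical(nrow(df))
  class(df) <- c("ceus_cohort", "data.frame")
  df
}

# ASCII PPM (P3) codec: lossless plain text for 8-bit RGB. Hand-rolled on
# purpose: no installed R package reads the format and it keeps frame
# fixtures human-inspectable.
.write_ppm <- function(frame, path) {
  d <- dim(frame)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), "255"), con)
  # row-major pixel order, channels interleaved
  vals <- as.integer(round(aperm(frame, c(3, 2, 1))))
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

.read_ppm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P3") .stop_invalid("not an ASCII PPM (P3) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != 3 * w * h) .stop_invalid("corrupt PPM payload: ", path)
  aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
}

#' Write / read a frame sequence as a directory of ASCII-PPM images
#'
#' One `frame_NNNN.ppm` per time point, the ROI as `roi_mask.pbm`
#' (ASCII PBM, 1 = inside), and a `sidecar.json` holding the frame times,
#' the seed and the file listing.
#'
#' @param frames a `"ceus_frames"` object.
#' @param dir output directory (created if needed).
#' @export
write_frames <- function(frames, dir) {
  if (!inherits(frames, "ceus_frames"))
    .stop_invalid("`frames` must be a ceus_frames object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("frame_%04d.ppm", seq_along(frames$frames))
  for (i in seq_along(frames$frames))
    .write_ppm(frames$frames[[i]], file.path(dir, files[i]))
  roi <- frames$roi_mask
  con <- file(file.path(dir, "roi_mask.pbm"), "w")
  writeLines(c("P1", paste(ncol(roi), nrow(roi)),
               paste(as.integer(t(roi)), collapse = " ")), con)
  close(con)
  jsonlite::write_json(
    list(times = frames$times, seed = frames$seed, frames = files,
         image_shape = dim(roi)),
    file.path(dir, "sidecar.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  tok <- scan(file.path(dir, "roi_mask.pbm"), what = character(),
              quiet = TRUE, comment.char = "#")
  if (tok[1] != "P1") .stop_invalid("roi_mask.pbm is not an ASCII PBM file")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  roi <- matrix(as.integer(tok[-(1:3)]) == 1L, nrow = h, byrow = TRUE)
  frames <- lapply(file.path(dir, side$frames), .read_ppm)
  structure(list(times = as.numeric(side$times), frames = frames,
                 roi_mask = roi,
                 seed = if (is.null(side$seed)) NULL else side$seed),
            class = "ceus_frames")
}
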