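#' Image and table input/output
#'
#' Camera frames are exchanged as 16-bit grayscale TIFF (counts in
#' `[0, 65535]`); intensity-ratio images as 32-bit float grayscale TIFF.
#' Since the float TIFF convention stores values in the unit interval, IR
#' values (which live near 1) are stored at half scale — an exact
#' operation in binary floating point for any IR below 2 — and rescaled
#' transparently on read. Detections and ground truth travel as plain
#' CSV.
#'
#' @name panorama-io
NULL

#' Write / read a camera frame as 16-bit grayscale TIFF
#'
#' @param image Numeric matrix of camera counts; values are clamped to
#'   `[0, 65535]` and quantized to 16 bits.
#' @param path TIFF file path.
#' @return `write_frame_tiff` returns `path` invisibly;
#'   `read_frame_tiff` the counts matrix.
#' @export
write_frame_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  x <- pmin(pmax(image, 0), 65535) / 65535
  tiff::writeTIFF(x, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x * 65535
}

#' Write / read an intensity-ratio image as 32-bit float TIFF
#'
#' Masked (`NA`) pixels are stored as 0 and restored to `NA` on read
#' (valid IR values are strictly positive).
#'
#' @param ir A [ratiometric()] image or a bare IR matrix.
#' @param path TIFF file path.
#' @return `write_ir_tiff` returns `path` invisibly; `read_ir_tiff` an IR
#'   matrix with `NA` at masked pixels.
#' @export
write_ir_tiff <- function(ir, path) {
  m <- if (inherits(ir, "ratiometric_image")) ir$ir else ir
  stopifnot(is.matrix(m))
  if (any(m >= 2, na.rm = TRUE))
    stop("IR >= 2 cannot be stored in the half-scale float encoding")
  m[is.na(m)] <- 0
  tiff::writeTIFF(m / 2, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_ir_tiff
#' @export
read_ir_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  x <- tiff::readTIFF(path) * 2
  x[x == 0] <- NA_real_
  x
}

#' Write / read a detection table as CSV
#'
#' @param detections Detection data frame (see [detect_particles()]).
#' @param path CSV file path.
#' @return `write_detections_csv` returns `path` invisibly;
#'   `read_detections_csv` the data frame.
#' @export
write_detections_csv <- function(detections, path) {
  stopifnot(is.data.frame(detections))
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  if (!file.exists(path)) stop("CSV not found: ", path)
  utils::read.csv(path)
}

#' Write the ground-truth particle table of a synthetic series
#'
#' @param series An [make_series()] acquisition series.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(series, path) {
  stopifnot(inherits(series, "acquisition_series"))
  utils::write.csv(series$truth, path, row.names = FALSE)
  invisible(path)
}
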