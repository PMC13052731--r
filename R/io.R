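# TIFF / JSON sidecar I/O for synthetic and measured data.
#
# Images are written as 32-bit float TIFF so synthetic intensities survive
# round-trips unchanged; ground truth goes to a `<stem>.truth.json`
# sidecar next to the image.

#' Write a 2D image (or list of frames) as TIFF
#'
#' Multi-frame input produces a multi-page TIFF. TIFF float storage holds
#' values in \[0, 1\], so intensities are divided by `scale` before
#' writing; the scale used is returned (record it in the truth sidecar to
#' restore native intensities on read).
#'
#' @param image numeric matrix, or list of matrices (pages).
#' @param path output file.
#' @param scale divisor applied before writing; defaults to
#'   `max(1, max(image))` so arbitrary non-negative intensities fit.
#' @return the scale used, invisibly.
#' @export
write_image_tiff <- function(image, path, scale = NULL) {
  pages <- if (is.list(image)) image else list(image)
  mx <- max(vapply(pages, max, numeric(1)))
  mn <- min(vapply(pages, min, numeric(1)))
  if (mn < 0) stop("negative intensities cannot be stored; shift first")
  scale <- scale %||% max(1, mx)
  pages <- lapply(pages, function(p) p / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' Write a z-stack (row x col x z array) as multi-page TIFF
#'
#' @param stack 3D numeric array.
#' @param path output file.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z])
  write_image_tiff(pages, path)
}

#' Read a TIFF as matrix (single page) or 3D array (multi-page)
#'
#' @param path TIFF file.
#' @return numeric matrix or row x col x z array.
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1) return(pages[[1]])
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write a ground-truth sidecar as JSON
#'
#' Matrices (e.g. label maps) are stored as nested arrays; the sidecar
#' round-trips losslessly via [read_truth_json()].
#'
#' @param truth list of ground-truth entries.
#' @param path output file (conventionally `<stem>.truth.json`).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path JSON file written by [write_truth_json()].
#' @return list.
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
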