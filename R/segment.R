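#' Segment nuclei in a 2D single-channel image
#'
#' Foreground is separated from background by Otsu thresholding of the
#' intensity histogram (or a fixed threshold override), holes inside nuclei
#' are filled, touching objects are optionally split by a watershed on the
#' distance transform, and objects below a minimum area are discarded.
#' Surviving objects are relabelled with consecutive positive integers.
#'
#' @param image 2D numeric matrix with finite values.
#' @param min_area_px minimum retained object area in pixels (default 50).
#' @param split_touching if `TRUE`, apply a distance-transform watershed to
#'   split touching nuclei.
#' @param threshold optional fixed intensity threshold overriding Otsu.
#' @param h watershed tolerance (h-maxima depth) in pixels, default 2.
#' @param fill_holes fill holes inside objects before measurement (the
#'   texture statistics need the full interior), default `TRUE`.
#' @param pixel_size_um physical pixel size carried into the result.
#' @return An object of class `nuclei_field`: list with `label_map`
#'   (integer matrix, 0 = background), `regions` (data.frame with `label`,
#'   0-based `centroid_row`/`centroid_col`, `area_px`, and half-open
#'   0-based bbox `rmin`/`rmax`/`cmin`/`cmax`), and `pixel_size_um`.
#' @export
segment_nuclei <- function(image, min_area_px = 50, split_touching = FALSE,
                           threshold = NULL, h = 2, fill_holes = TRUE,
                           pixel_size_um = 1) {
  if (length(dim(image)) != 2) stop("image must be a 2D matrix")
  if (!all(is.finite(image))) stop("image must contain finite values only")
  rng <- range(image)
  if (rng[2] <= rng[1]) {
    # constant image: no objects, not an error
    return(new_nuclei_field(matrix(0L, nrow(image), ncol(image)),
                            pixel_size_um))
  }
  th <- threshold %||% otsu_threshold(image)
  bw <- image > th
  if (fill_holes) {
    bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw))) > 0
  }
  if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(bw))
    lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = h))
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  }
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  # area filter + consecutive relabelling
  if (max(lab) > 0) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= min_area_px)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    nz <- lab > 0
    lab[nz] <- remap[lab[nz]]
  }
  new_nuclei_field(lab, pixel_size_um)
}

# Build a nuclei_field (label map + region table) from an integer label map.
new_nuclei_field <- function(label_map, pixel_size_um = 1) {
  n <- max(label_map)
  if (n > 0) {
    idx <- which(label_map > 0)
    lab <- label_map[idx]
    rows <- (idx - 1L) %% nrow(label_map)   # 0-based
    cols <- (idx - 1L) %/% nrow(label_map)
    area <- tabulate(lab, nbins = n)
    f <- factor(lab, levels = seq_len(n))  # keep numeric label order
    regions <- data.frame(
      label = seq_len(n),
      centroid_row = as.numeric(tapply(rows, f, mean)),
      centroid_col = as.numeric(tapply(cols, f, mean)),
      area_px = area,
      rmin = as.integer(tapply(rows, f, min)),
      rmax = as.integer(tapply(rows, f, max)) + 1L,  # half-open
      cmin = as.integer(tapply(cols, f, min)),
      cmax = as.integer(tapply(cols, f, max)) + 1L)
  } else {
    regions <- data.frame(label = integer(0), centroid_row = numeric(0),
                          centroid_col = numeric(0), area_px = integer(0),
                          rmin = integer(0), rmax = integer(0),
                          cmin = integer(0), cmax = integer(0))
  }
  structure(list(label_map = label_map, regions = regions,
                 pixel_size_um = pixel_size_um),
            class = "nuclei_field")
}

#' Extract the logical mask of one labelled object
#'
#' @param field a `nuclei_field`.
#' @param label object label.
#' @return logical matrix the size of the field.
#' @export
region_mask <- function(field, label) {
  stopifnot(inherits(field, "nuclei_field"))
  field$label_map == label
}

#' Count cells (nuclei) in an image
#'
#' Segments the image as [segment_nuclei()] and returns the number of
#' retained objects.
#'
#' @inheritParams segment_nuclei
#' @param ... passed on to [segment_nuclei()].
#' @return integer count.
#' @export
count_cells <- function(image, min_area_px = 50, ...) {
  nrow(segment_nuclei(image, min_area_px = min_area_px, ...)$regions)
}

#' @export
print.nuclei_field <- function(x, ...) {
  cat("nuclei_field:", nrow(x$regions), "objects,",
      paste(dim(x$label_map), collapse = " x "), "px, pixel size",
      x$pixel_size_um, "um\n")
  invisible(x)
}

#' Write a label map as 16-bit TIFF
#'
#' @param field a `nuclei_field`.
#' @param path output file.
#' @export
write_label_tiff <- function(field, path) {
  stopifnot(inherits(field, "nuclei_field"))
  tiff::writeTIFF(field$label_map / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
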