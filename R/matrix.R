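#' Nascent matrix area per nucleus
#'
#' Otsu-thresholds the nascent-matrix channel, removes speckles below
#' `min_area_px`, sums the remaining foreground area, counts nuclei in the
#' nuclei channel via [count_cells()], and returns the ratio. A saturation
#' QC flag is raised when more than 20% of the matrix foreground sits at
#' the channel maximum (dense-region overlap makes such fields
#' unreliable to quantify).
#'
#' @param matrix_channel 2D numeric matrix (nascent-matrix stain).
#' @param nuclei_channel 2D numeric matrix, same shape (nuclear stain).
#' @param min_area_px minimum object area, used both for matrix speckle
#'   removal and nucleus counting (default 50).
#' @return object of class `matrix_result`: list with `matrix_area_px2`,
#'   `n_nuclei`, `area_per_nucleus`, `saturation_flag`.
#' @export
matrix_area_per_nucleus <- function(matrix_channel, nuclei_channel,
                                    min_area_px = 50) {
  if (!identical(dim(matrix_channel), dim(nuclei_channel))) {
    stop("channels must have the same shape")
  }
  n_nuc <- count_cells(nuclei_channel, min_area_px = min_area_px)
  if (n_nuc == 0) stop("no nuclei found; ratio undefined")
  rng <- range(matrix_channel)
  if (rng[2] <= rng[1]) {
    area <- 0
    sat <- FALSE
  } else {
    fg <- matrix_channel > otsu_threshold(matrix_channel)
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg)))
    lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      fg <- fg & matrix(sizes[pmax(lab, 1L)] >= min_area_px & lab > 0,
                        nrow(fg), ncol(fg))
    }
    area <- sum(fg)
    sat <- if (area > 0) {
      mean(matrix_channel[fg] >= rng[2]) > 0.2
    } else FALSE
  }
  structure(list(matrix_area_px2 = as.numeric(area), n_nuclei = n_nuc,
                 area_per_nucleus = as.numeric(area) / n_nuc,
                 saturation_flag = sat),
            class = "matrix_result")
}

#' @export
print.matrix_result <- function(x, ...) {
  cat("matrix_result:", x$matrix_area_px2, "px^2 over", x$n_nuclei,
      "nuclei =", signif(x$area_per_nucleus, 5), "px^2/nucleus",
      if (x$saturation_flag) "(saturation QC flag)" else "", "\n")
  invisible(x)
}
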