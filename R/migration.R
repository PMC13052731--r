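# 3D interstitial migration scoring and 2D scratch-closure kinetics.
#
# Depth convention: z increases into the stack; depth = cell z - interface
# z, so positive depth means the cell is inside the tissue. Flipping the
# stack in z therefore negates depths.

#' Detect the tissue interface plane in a z-stack
#'
#' Computes the per-plane tissue occupancy fraction (Otsu-binarized over
#' the whole channel) and returns the first z, linearly interpolated
#' between planes, at which occupancy crosses half its plateau (maximum)
#' value. Works for either orientation (tissue at the bottom or, for a
#' z-flipped stack, at the top).
#'
#' @param tissue_channel 3D numeric array (row, col, z), >= 3 planes.
#' @param z_step_um z spacing in micrometres (> 0).
#' @return interface z in micrometres (plane 1 is z = 0), with the
#'   per-plane `occupancy` profile attached as an attribute.
#' @export
detect_interface <- function(tissue_channel, z_step_um) {
  stopifnot(length(dim(tissue_channel)) == 3)
  if (z_step_um <= 0) stop("z_step_um must be positive")
  nz <- dim(tissue_channel)[3]
  if (nz < 3) stop("stack must have at least 3 planes")
  rng <- range(tissue_channel)
  if (rng[2] <= rng[1]) stop("tissue channel is constant; no interface")
  th <- otsu_threshold(tissue_channel)
  occ <- apply(tissue_channel > th, 3, mean)
  plateau <- max(occ)
  half <- plateau / 2
  z <- (seq_len(nz) - 1) * z_step_um
  above0 <- occ[1] >= half
  cross <- NA_integer_
  for (k in 2:nz) {
    if ((occ[k] >= half) != above0) { cross <- k; break }
  }
  if (is.na(cross)) stop("occupancy never crosses half its plateau value")
  # linear interpolation between planes cross-1 and cross
  o1 <- occ[cross - 1]; o2 <- occ[cross]
  zi <- z[cross - 1] + (half - o1) / (o2 - o1) * z_step_um
  structure(zi, occupancy = occ)
}

#' Detect cells in a migration stack and score infiltration depth
#'
#' Cells are found as 3D local maxima of the Gaussian-smoothed cell
#' channel above an intensity threshold, with close maxima suppressed
#' (minimum separation twice the blob radius). Each detection is refined
#' by an intensity-weighted centroid over its blob window; depth is the
#' centroid z minus the interface z. A cell is called embedded when its
#' depth is at least `embed_margin_um`, the margin standing in for
#' "entirely inside the tissue" given the blob radius.
#'
#' @param stack a migration stack as produced by [gen_migration_stack()]
#'   or a list with `cell_channel`, `tissue_channel`, `z_step_um`,
#'   `pixel_size_um`, and optionally `blob_radius_um`.
#' @param embed_margin_um depth margin for the embedded call; defaults to
#'   the stack's blob radius.
#' @param interface_z_um interface depth; detected with
#'   [detect_interface()] when `NULL`.
#' @param intensity_frac detection threshold as a fraction of the smoothed
#'   channel maximum (default 0.3).
#' @return data.frame of class `migration_cells` with `x_um`, `y_um`,
#'   `z_um`, `depth_um`, `embedded`; the interface used is attached as
#'   attribute `interface_z_um`.
#' @export
score_cells <- function(stack, embed_margin_um = NULL,
                        interface_z_um = NULL, intensity_frac = 0.3) {
  cellch <- stack$cell_channel
  stopifnot(length(dim(cellch)) == 3)
  zs <- stack$z_step_um
  px <- stack$pixel_size_um %||% 1
  rb <- stack$blob_radius_um %||% (2 * zs)
  margin <- embed_margin_um %||% rb
  zi <- interface_z_um %||% detect_interface(stack$tissue_channel, zs)
  d <- dim(cellch)
  sig_xy <- rb / px / 2; sig_z <- rb / zs / 2
  sm <- gauss_smooth3(cellch, c(sig_xy, sig_xy, sig_z))
  mx <- max(sm)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), depth_um = numeric(0),
                      embedded = logical(0))
  if (mx <= 0) {
    return(structure(empty, interface_z_um = as.numeric(zi),
                     class = c("migration_cells", "data.frame")))
  }
  th <- intensity_frac * mx
  # 26-neighbourhood local maxima above threshold
  is_max <- sm > th
  for (dr in -1:1) for (dc in -1:1) for (dz in -1:1) {
    if (dr == 0 && dc == 0 && dz == 0) next
    ri <- pmin(pmax(seq_len(d[1]) + dr, 1L), d[1])
    ci <- pmin(pmax(seq_len(d[2]) + dc, 1L), d[2])
    zi2 <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    is_max <- is_max & (sm >= sm[ri, ci, zi2])
    if (!any(is_max)) break
  }
  pk <- which(is_max, arr.ind = TRUE)
  if (nrow(pk) == 0) {
    return(structure(empty, interface_z_um = as.numeric(zi),
                     class = c("migration_cells", "data.frame")))
  }
  inten <- sm[pk]
  ord <- order(inten, decreasing = TRUE)
  pk <- pk[ord, , drop = FALSE]
  # suppress maxima closer than 2 blob radii (in um, anisotropy respected)
  keep <- rep(TRUE, nrow(pk))
  pos_um <- cbind((pk[, 1] - 1) * px, (pk[, 2] - 1) * px,
                  (pk[, 3] - 1) * zs)
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      j <- (i + 1):nrow(pk)
      dd <- sqrt((pos_um[j, 1] - pos_um[i, 1])^2 +
                 (pos_um[j, 2] - pos_um[i, 2])^2 +
                 (pos_um[j, 3] - pos_um[i, 3])^2)
      keep[j][dd < 2 * rb] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  # intensity-weighted centroid refinement in a blob-sized window
  wr <- max(1L, round(1.5 * rb / px)); wz <- max(1L, round(1.5 * rb / zs))
  cells <- lapply(seq_len(nrow(pk)), function(i) {
    r0 <- pk[i, 1]; c0 <- pk[i, 2]; z0 <- pk[i, 3]
    rs <- max(1L, r0 - wr):min(d[1], r0 + wr)
    cs <- max(1L, c0 - wr):min(d[2], c0 + wr)
    zs2 <- max(1L, z0 - wz):min(d[3], z0 + wz)
    w <- sm[rs, cs, zs2, drop = FALSE]
    tot <- sum(w)
    rg <- sum(apply(w, 1, sum) * rs) / tot
    cg <- sum(apply(w, 2, sum) * cs) / tot
    zg <- sum(apply(w, 3, sum) * zs2) / tot
    data.frame(x_um = (cg - 1) * px, y_um = (rg - 1) * px,
               z_um = (zg - 1) * zs)
  })
  cells <- do.call(rbind, cells)
  cells$depth_um <- cells$z_um - as.numeric(zi)
  cells$embedded <- cells$depth_um >= margin
  structure(cells, interface_z_um = as.numeric(zi),
            class = c("migration_cells", "data.frame"))
}

#' Percent of migrated (fully embedded) cells
#'
#' Number of embedded cells divided by the number of cells in the field of
#' view, times 100.
#'
#' @param cells data.frame with a logical `embedded` column.
#' @return percent in \[0, 100\].
#' @export
percent_migrated <- function(cells) {
  if (nrow(cells) == 0) stop("no cells in field of view")
  100 * sum(cells$embedded) / nrow(cells)
}

#' Cumulative frequency curve of migration depths
#'
#' Nondecreasing percent-of-cells-at-or-above curve over depth bins,
#' ending at 100%.
#'
#' @param depths_um finite numeric depths.
#' @param bin_edges optional ascending bin edges; defaults to the sorted
#'   unique depths. An edge at the maximum depth is appended if needed so
#'   the curve always ends at 100%.
#' @return data.frame with `depth_um` and `cum_pct`.
#' @export
cumulative_frequency <- function(depths_um, bin_edges = NULL) {
  if (length(depths_um) == 0) stop("no depths supplied")
  if (!all(is.finite(depths_um))) stop("depths must be finite")
  edges <- sort(bin_edges %||% unique(sort(depths_um)))
  if (length(edges) == 0 || max(edges) < max(depths_um)) {
    edges <- c(edges, max(depths_um))
  }
  data.frame(depth_um = edges,
             cum_pct = vapply(edges,
                              function(e) 100 * mean(depths_um <= e),
                              numeric(1)))
}

#' Scratch (cell-free void) area of a wound-assay frame
#'
#' The void is detected by texture, not raw brightness: a local
#' intensity-variance map (box window) is Otsu-thresholded, the
#' low-variance mask is morphologically closed and then dilated by the
#' window half-width (compensating the half-window erosion a windowed
#' variance imposes at texture/void boundaries), and the largest connected
#' low-variance component spanning the frame height is returned.
#'
#' @param image 2D numeric matrix.
#' @param var_window odd box window for the local variance (default 7).
#' @param min_height_frac minimum fraction of frame height a component
#'   must span to count as the scratch (default 0.9).
#' @return area in px^2 (0 with attribute `found = FALSE` when no void
#'   component spans the frame).
#' @export
scratch_area <- function(image, var_window = 7L, min_height_frac = 0.9) {
  stopifnot(length(dim(image)) == 2)
  k <- matrix(1, var_window, var_window) / var_window^2
  m1 <- EBImage::imageData(EBImage::filter2(EBImage::Image(image), k,
                                            boundary = "replicate"))
  m2 <- EBImage::imageData(EBImage::filter2(EBImage::Image(image^2), k,
                                            boundary = "replicate"))
  v <- pmax(m2 - m1^2, 0)
  th <- otsu_threshold(v)
  low <- v < th
  # a real void is near-textureless: its variance level must sit far below
  # the cell-texture class, otherwise the split is just texture noise
  if (mean(v[low]) > 0.2 * mean(v[!low])) return(structure(0, found = FALSE))
  half <- (var_window - 1L) / 2L
  br_close <- EBImage::makeBrush(5L, "box")
  br_dilate <- EBImage::makeBrush(2L * half + 1L, "box")
  low <- EBImage::imageData(EBImage::closing(EBImage::Image(low),
                                             br_close)) > 0
  low <- EBImage::imageData(EBImage::dilate(EBImage::Image(low),
                                            br_dilate)) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(low)))
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  n <- max(lab)
  if (n == 0) return(structure(0, found = FALSE))
  best <- 0
  for (i in seq_len(n)) {
    rows <- which(rowSums(lab == i) > 0)
    if ((max(rows) - min(rows) + 1) >= min_height_frac * nrow(image)) {
      best <- max(best, sum(lab == i))
    }
  }
  if (best == 0) return(structure(0, found = FALSE))
  structure(as.numeric(best), found = TRUE)
}

#' Scratch closure rate from a measured series
#'
#' Ordinary least-squares slope of scratch area against time over the
#' frames preceding the first fully closed (zero-area) frame.
#'
#' @param times_h hours, strictly increasing.
#' @param areas_px2 scratch areas per frame (>= 0).
#' @return slope in area units per hour (negative for a closing wound),
#'   with `n_frames_used` attached.
#' @export
closure_rate <- function(times_h, areas_px2) {
  stopifnot(length(times_h) == length(areas_px2), all(areas_px2 >= 0))
  if (is.unsorted(times_h, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  first_zero <- which(areas_px2 == 0)[1]
  use <- if (is.na(first_zero)) seq_along(times_h) else seq_len(first_zero - 1)
  if (length(use) < 2) stop("fewer than 2 pre-closure frames")
  fit <- stats::lm(a ~ t, data = data.frame(t = times_h[use],
                                            a = areas_px2[use]))
  structure(unname(stats::coef(fit)[2]), n_frames_used = length(use))
}
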