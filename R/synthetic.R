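#' Specification for a synthetic DAPI nucleus field
#'
#' Bundles the knobs of the nucleus-field generator. Nuclei are rendered as
#' non-overlapping ellipses fully inside the frame, with punctate
#' heterochromatin foci whose contrast is controlled by `condensation`:
#' at 0 the nuclear interior is uniform (fully decondensed chromatin), at 1
#' the foci are at full contrast, so expected within-nucleus intensity
#' variance increases strictly with the knob.
#'
#' @param image_shape integer (rows, cols) of the frame in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param radius_px mean nucleus radius in pixels (>= 3).
#' @param condensation unitless in \[0, 1\]; scales heterochromatin foci
#'   contrast (1 = condensed, 0 = fully decondensed).
#' @param foci_per_nucleus number of heterochromatin foci per nucleus.
#' @param noise_sd additive Gaussian noise SD in intensity units (0 = off).
#' @param nar_range range of true nuclear aspect ratios to draw from;
#'   `c(1, 1)` gives circles.
#' @param seed integer RNG seed; identical spec + seed reproduce the field
#'   bit-for-bit.
#' @return A list of class `nucleus_field_spec`.
#' @export
nucleus_field_spec <- function(image_shape = c(256L, 256L), n_nuclei = 25L,
                               radius_px = 12, condensation = 0.5,
                               foci_per_nucleus = 8L, noise_sd = 0,
                               nar_range = c(1, 1.3), seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8),
            n_nuclei >= 0, radius_px >= 3,
            condensation >= 0, condensation <= 1,
            foci_per_nucleus >= 0, noise_sd >= 0,
            length(nar_range) == 2, all(nar_range >= 1))
  structure(list(image_shape = as.integer(image_shape),
                 n_nuclei = as.integer(n_nuclei), radius_px = radius_px,
                 condensation = condensation,
                 foci_per_nucleus = as.integer(foci_per_nucleus),
                 noise_sd = noise_sd, nar_range = nar_range,
                 seed = as.integer(seed)),
            class = "nucleus_field_spec")
}

# Rasterize ellipse k into img/label and add its foci texture.
# Returns the modified (img, label) pair. 1-based pixel-centre coordinates.
render_nucleus <- function(img, label, k, r0, c0, a, b, theta, foci,
                           base_int, foci_amp, foci_sigma) {
  nr <- nrow(img); nc <- ncol(img)
  rmin <- max(1L, floor(r0 - a)); rmax <- min(nr, ceiling(r0 + a))
  cmin <- max(1L, floor(c0 - a)); cmax <- min(nc, ceiling(c0 + a))
  rs <- rmin:rmax; cs <- cmin:cmax
  dy <- matrix(rs - r0, length(rs), length(cs))
  dx <- matrix(cs - c0, length(rs), length(cs), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  rho2 <- u * u + v * v
  inside <- rho2 <= 1
  # smooth radial dome: DAPI nuclei are brighter at the centre; this also
  # anchors the per-nucleus intensity range independently of foci contrast
  tex <- base_int + 0.12 * (1 - rho2)
  if (nrow(foci) > 0 && foci_amp > 0) {
    for (f in seq_len(nrow(foci))) {
      d2 <- (dy - foci[f, "dr"])^2 + (dx - foci[f, "dc"])^2
      tex <- tex + foci_amp * foci[f, "w"] * exp(-d2 / (2 * foci_sigma^2))
    }
  }
  sub_img <- img[rs, cs]; sub_lab <- label[rs, cs]
  sub_img[inside] <- tex[inside]
  sub_lab[inside] <- k
  img[rs, cs] <- sub_img
  label[rs, cs] <- sub_lab
  list(img = img, label = label)
}

#' Generate a synthetic DAPI nucleus field with ground truth
#'
#' Places `n_nuclei` non-overlapping elliptical nuclei fully inside the
#' frame and renders each as a uniform interior plus sum-of-Gaussian
#' heterochromatin foci. The `condensation` knob models chromatin
#' decondensation the way it appears in DAPI images: as condensation
#' drops, foci lose amplitude and broaden (texture smooths out), so both
#' the within-nucleus intensity variance and the internal edge density
#' fall. Deterministic under a fixed seed.
#'
#' @param spec a [nucleus_field_spec()].
#' @param max_attempts rejection-sampling attempts per nucleus before a
#'   placement error is raised.
#' @return list with `image` (numeric matrix) and `truth`, a list carrying
#'   `label_map`, 0-based `centroids` (row, col), per-nucleus ellipse
#'   `params` (centre, semi-axes, orientation), `true_nar`, and `n`.
#' @export
gen_nucleus_field <- function(spec, max_attempts = 500L,
                              placement_shrink = c(1, 1)) {
  stopifnot(inherits(spec, "nucleus_field_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  # centres are confined to the central placement_shrink fraction of the
  # frame (strain series use this so stretched nuclei stay in view)
  half_r <- nr * placement_shrink[1] / 2
  half_c <- nc * placement_shrink[2] / 2
  n <- spec$n_nuclei
  with_seed(spec$seed, {
    img <- matrix(0, nr, nc)
    label <- matrix(0L, nr, nc)
    cent <- matrix(numeric(0), 0, 2,
                   dimnames = list(NULL, c("row", "col")))
    params <- data.frame(row0 = numeric(0), col0 = numeric(0),
                         a = numeric(0), b = numeric(0), theta = numeric(0))
    if (n > 0) {
      nar <- runif(n, spec$nar_range[1], spec$nar_range[2])
      rad <- spec$radius_px * runif(n, 0.9, 1.1)
      a <- rad * sqrt(nar); b <- rad / sqrt(nar)
      theta <- runif(n, 0, pi)
      r0 <- c0 <- numeric(n)
      for (k in seq_len(n)) {
        m <- a[k] + 2
        if (2 * m >= min(nr, nc)) {
          stop("frame too small to place nucleus of radius ", round(a[k], 1))
        }
        ctr_r <- (nr + 1) / 2; ctr_c <- (nc + 1) / 2
        lo_r <- max(1 + m, ctr_r - half_r + m)
        hi_r <- min(nr - m, ctr_r + half_r - m)
        lo_c <- max(1 + m, ctr_c - half_c + m)
        hi_c <- min(nc - m, ctr_c + half_c - m)
        if (lo_r >= hi_r || lo_c >= hi_c) {
          stop("placement region too small for nucleus radius ",
               round(a[k], 1))
        }
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          rr <- runif(1, lo_r, hi_r)
          cc <- runif(1, lo_c, hi_c)
          if (k == 1 || all(sqrt((rr - r0[seq_len(k - 1)])^2 +
                                 (cc - c0[seq_len(k - 1)])^2) >
                            a[k] + a[seq_len(k - 1)] + 2)) {
            r0[k] <- rr; c0[k] <- cc; placed <- TRUE; break
          }
        }
        if (!placed) {
          stop("placement failed: frame too crowded for ", n, " nuclei")
        }
      }
      foci_sigma <- pmax(1, rad / 8)
      for (k in seq_len(n)) {
        nf <- spec$foci_per_nucleus
        if (nf > 0) {
          # foci uniform in the inner 75% of the ellipse, in its own frame
          rho <- sqrt(runif(nf)) * 0.75
          ang <- runif(nf, 0, 2 * pi)
          u <- rho * cos(ang) * a[k]; v <- rho * sin(ang) * b[k]
          foci <- cbind(dr = u * sin(theta[k]) + v * cos(theta[k]),
                        dc = u * cos(theta[k]) - v * sin(theta[k]),
                        w = runif(nf, 0.8, 1.2))
        } else {
          foci <- cbind(dr = numeric(0), dc = numeric(0), w = numeric(0))
        }
        # decondensed chromatin: dimmer AND broader foci (smoother texture)
        res <- render_nucleus(img, label, k, r0[k], c0[k], a[k], b[k],
                              theta[k], foci, base_int = 0.5,
                              foci_amp = 0.4 * spec$condensation,
                              foci_sigma = foci_sigma[k] *
                                (1 + 0.8 * (1 - spec$condensation)))
        img <- res$img; label <- res$label
      }
      cent <- cbind(row = r0 - 1, col = c0 - 1)  # 0-based pixel coords
      params <- data.frame(row0 = r0, col0 = c0, a = a, b = b, theta = theta)
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    truth <- list(label_map = label, centroids = cent, params = params,
                  true_nar = params$a / params$b, n = n)
    list(image = img, truth = truth)
  })
}

# True covariance-shape of nucleus k (proportional to second moments),
# in (x = col, y = row) coordinates.
ellipse_cov <- function(a, b, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  R %*% diag(c(a^2, b^2)) %*% t(R)
}

#' Generate a strain series by plane-strain resampling of a nucleus field
#'
#' Renders a base field and, for each applied engineering strain, resamples
#' the frame under the affine map that stretches the frame by `(1 + strain)`
#' along the stretch axis with a configurable transverse contraction
#' (default area-preserving, factor `1/(1 + strain)`). True per-nucleus
#' aspect ratios under each map are recorded in the ground truth.
#'
#' @param base_spec a [nucleus_field_spec()] for the unstrained frame.
#' @param strains numeric vector of engineering strains, ascending, first
#'   element 0; negative strains are rejected.
#' @param transverse `"area"` (area-preserving, default), `"none"` (no
#'   contraction), or a function of strain returning the transverse factor.
#' @param axis `"col"` (default) or `"row"`: image axis of applied stretch.
#' @return list with `images` (one matrix per strain), `strains`, and
#'   `truth`: per-frame `label_map`, 0-based `centroids` and `true_nar`,
#'   with nucleus index as the persistent track id.
#' @export
gen_strain_series <- function(base_spec, strains, transverse = "area",
                              axis = c("col", "row")) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(strains), length(strains) >= 1)
  if (any(strains < 0)) stop("negative strain is not supported")
  if (strains[1] != 0) stop("first strain level must be 0")
  if (is.unsorted(strains, strictly = TRUE)) {
    stop("strains must be strictly ascending")
  }
  tfun <- if (is.function(transverse)) {
    transverse
  } else if (identical(transverse, "area")) {
    function(e) 1 / (1 + e)
  } else if (identical(transverse, "none")) {
    function(e) 1
  } else stop("transverse must be 'area', 'none', or a function")

  # confine placement so every nucleus stays in frame at maximum stretch
  fmax_col <- max(vapply(strains, function(e) {
    if (axis == "col") 1 + e else tfun(e)
  }, numeric(1)))
  fmax_row <- max(vapply(strains, function(e) {
    if (axis == "row") 1 + e else tfun(e)
  }, numeric(1)))
  base <- gen_nucleus_field(base_spec,
                            placement_shrink = c(1 / max(1, fmax_row),
                                                 1 / max(1, fmax_col)))
  nr <- nrow(base$image); nc <- ncol(base$image)
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  grid_r <- matrix(seq_len(nr), nr, nc)
  grid_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  images <- vector("list", length(strains))
  frames <- vector("list", length(strains))
  for (i in seq_along(strains)) {
    e <- strains[i]
    s_axis <- 1 + e; s_perp <- tfun(e)
    s_col <- if (axis == "col") s_axis else s_perp
    s_row <- if (axis == "row") s_axis else s_perp
    # inverse map: sample source at (r - r0)/s_row, (c - c0)/s_col
    src_r <- (grid_r - r0) / s_row + r0
    src_c <- (grid_c - c0) / s_col + c0
    images[[i]] <- matrix(bilinear_sample(base$image, src_r, src_c),
                          nr, nc)
    lab <- matrix(0L, nr, nc)
    ri <- round(src_r); ci <- round(src_c)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    lab[ok] <- base$truth$label_map[cbind(ri[ok], ci[ok])]
    p <- base$truth$params
    if (nrow(p) > 0) {
      M <- diag(c(s_col, s_row))  # (x, y) = (col, row)
      tn <- vapply(seq_len(nrow(p)), function(k) {
        C <- M %*% ellipse_cov(p$a[k], p$b[k], p$theta[k]) %*% M
        ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
        sqrt(ev[1] / ev[2])
      }, numeric(1))
      cent <- cbind(row = (p$row0 - r0) * s_row + r0 - 1,
                    col = (p$col0 - c0) * s_col + c0 - 1)
    } else {
      tn <- numeric(0)
      cent <- matrix(numeric(0), 0, 2,
                     dimnames = list(NULL, c("row", "col")))
    }
    frames[[i]] <- list(label_map = lab, centroids = cent, true_nar = tn)
  }
  list(images = images, strains = strains,
       truth = list(frames = frames, base = base$truth,
                    transverse = if (is.function(transverse)) "custom"
                                 else transverse, axis = axis))
}

#' Generate a two-channel migration z-stack with known cell depths
#'
#' Emulates a confocal stack of fluorescently labelled cells over a
#' devitalized tissue section: the tissue channel occupies planes at
#' `z >= interface_z_um`, and cells are rendered as 3D Gaussian blobs at
#' sampled depths relative to the interface (positive depth = into tissue).
#' The default depth distribution is bimodal: surface-retained cells rest
#' on top of the section (centroid about one blob radius above the
#' interface) while infiltrated cells lie fully inside it — partially
#' embedded intermediates are transient in this assay and are not drawn.
#' A cell is flagged embedded in the ground truth iff its whole blob
#' support lies within the tissue, i.e. depth >= blob radius.
#'
#' @param n_cells number of cells (>= 0).
#' @param interface_z_um true tissue interface depth in micrometres.
#' @param z_step_um z spacing in micrometres (> 0).
#' @param frame_shape (rows, cols) of each plane in pixels.
#' @param pixel_size_um xy pixel size in micrometres.
#' @param blob_radius_um rendered cell blob radius in micrometres.
#' @param depth_distribution either the default bimodal surface/embedded
#'   mixture `list(name = "bimodal", frac_embedded, surface_sd_um,
#'   embed_spread_um)` or `list(name = "normal", mean_um, sd_um)`.
#' @param depths_um optional explicit per-cell depths (overrides the
#'   distribution).
#' @param n_embedded optional count of cells forced to be embedded under
#'   the bimodal model (overrides `frac_embedded`).
#' @param noise_sd additive Gaussian noise SD on both channels.
#' @param seed integer RNG seed.
#' @return list with `cell_channel` and `tissue_channel` (row x col x z
#'   arrays), `z_step_um`, `pixel_size_um`, `blob_radius_um`,
#'   `interface_z_um` (true), and `truth`: data frame of per-cell
#'   x/y/z (um), `depth_um` and `embedded`.
#' @export
gen_migration_stack <- function(n_cells, interface_z_um = 20, z_step_um = 2,
                                frame_shape = c(160L, 160L),
                                pixel_size_um = 1, blob_radius_um = 5,
                                depth_distribution = list(
                                  name = "bimodal", frac_embedded = 0.5,
                                  surface_sd_um = 1, embed_spread_um = 6),
                                depths_um = NULL, n_embedded = NULL,
                                noise_sd = 0, seed = 1L) {
  if (z_step_um <= 0) stop("z_step_um must be positive")
  stopifnot(n_cells >= 0, interface_z_um > z_step_um)
  nr <- frame_shape[1]; nc <- frame_shape[2]
  rb <- blob_radius_um
  with_seed(seed, {
    if (!is.null(depths_um)) {
      stopifnot(length(depths_um) == n_cells)
      depths <- as.numeric(depths_um)
    } else if (n_cells == 0) {
      depths <- numeric(0)
    } else if (identical(depth_distribution$name, "normal")) {
      depths <- rnorm(n_cells, depth_distribution$mean_um,
                      depth_distribution$sd_um)
    } else {
      if (!is.null(n_embedded)) {
        stopifnot(n_embedded >= 0, n_embedded <= n_cells)
        emb <- c(rep(TRUE, n_embedded), rep(FALSE, n_cells - n_embedded))
      } else {
        emb <- runif(n_cells) < (depth_distribution$frac_embedded %||% 0.5)
      }
      depths <- ifelse(
        emb,
        rb + 1 + abs(rnorm(n_cells, 0,
                           depth_distribution$embed_spread_um %||% 6)),
        rnorm(n_cells, -rb, depth_distribution$surface_sd_um %||% 1))
    }
    z_max <- interface_z_um + max(c(depths, 0)) + rb + 3 * z_step_um
    nz <- as.integer(ceiling(z_max / z_step_um)) + 1L
    z_planes <- (seq_len(nz) - 1) * z_step_um
    if (nz < 3) stop("stack must have at least 3 planes")

    # xy placement with minimum separation so blob maxima stay distinct
    rb_px <- rb / pixel_size_um
    min_sep <- 3 * rb_px
    xs <- ys <- numeric(n_cells)
    for (k in seq_len(n_cells)) {
      placed <- FALSE
      for (att in 1:500) {
        y <- runif(1, rb_px + 2, nr - rb_px - 1)
        x <- runif(1, rb_px + 2, nc - rb_px - 1)
        if (k == 1 || all(sqrt((x - xs[seq_len(k - 1)])^2 +
                               (y - ys[seq_len(k - 1)])^2) > min_sep)) {
          xs[k] <- x; ys[k] <- y; placed <- TRUE; break
        }
      }
      if (!placed) stop("placement failed: frame too crowded for cells")
    }

    cellch <- array(0, c(nr, nc, nz))
    sig_xy <- rb_px / 2
    sig_z <- rb / 2
    amp <- if (n_cells > 0) runif(n_cells, 0.8, 1.2) else numeric(0)
    zc <- interface_z_um + depths
    for (k in seq_len(n_cells)) {
      rwin <- max(1L, floor(ys[k] - 2 * rb_px)):min(nr, ceiling(ys[k] + 2 * rb_px))
      cwin <- max(1L, floor(xs[k] - 2 * rb_px)):min(nc, ceiling(xs[k] + 2 * rb_px))
      zwin <- which(abs(z_planes - zc[k]) <= 2.5 * rb)
      if (length(zwin) == 0) next
      dy2 <- (rwin - ys[k])^2
      dx2 <- (cwin - xs[k])^2
      g_xy <- outer(exp(-dy2 / (2 * sig_xy^2)), exp(-dx2 / (2 * sig_xy^2)))
      for (zi in zwin) {
        gz <- exp(-(z_planes[zi] - zc[k])^2 / (2 * sig_z^2))
        cellch[rwin, cwin, zi] <- cellch[rwin, cwin, zi] + amp[k] * g_xy * gz
      }
    }

    tissue <- array(0, c(nr, nc, nz))
    in_tissue <- z_planes >= interface_z_um
    if (any(in_tissue)) {
      tex <- matrix(runif(nr * nc, 0.5, 1), nr, nc)
      for (zi in which(in_tissue)) tissue[, , zi] <- tex
    }
    if (noise_sd > 0) {
      cellch <- cellch + array(rnorm(length(cellch), 0, noise_sd), dim(cellch))
      tissue <- tissue + array(rnorm(length(tissue), 0, noise_sd), dim(tissue))
    }
    truth <- data.frame(
      x_um = xs * pixel_size_um, y_um = ys * pixel_size_um, z_um = zc,
      depth_um = depths, embedded = depths >= rb)
    list(cell_channel = cellch, tissue_channel = tissue,
         z_step_um = z_step_um, pixel_size_um = pixel_size_um,
         blob_radius_um = rb, interface_z_um = interface_z_um,
         truth = truth)
  })
}

#' Generate a scratch-wound image time series with known void areas
#'
#' A confluent monolayer is emulated as high-variance speckle texture; the
#' scratch is a low-intensity vertical band through the frame centre whose
#' width shrinks linearly by `closure_px_per_frame` per frame until closed.
#'
#' @param frame_shape (rows, cols) in pixels.
#' @param initial_width_px scratch width at time 0 (< frame width).
#' @param closure_px_per_frame linear narrowing per frame in pixels.
#' @param n_frames number of frames.
#' @param dt_h hours between frames (imaging interval).
#' @param seed integer RNG seed.
#' @return list with `images`, `times_h`, and `truth` carrying
#'   `area_px2` (exact void area per frame) and `width_px`.
#' @export
gen_scratch_series <- function(frame_shape = c(400L, 600L),
                               initial_width_px = 100L,
                               closure_px_per_frame = 25,
                               n_frames = 5L, dt_h = 4, seed = 1L) {
  nr <- frame_shape[1]; nc <- frame_shape[2]
  if (initial_width_px >= nc) stop("initial width must be below frame width")
  stopifnot(n_frames >= 1, closure_px_per_frame >= 0)
  with_seed(seed, {
    widths <- pmax(0, initial_width_px -
                        closure_px_per_frame * (seq_len(n_frames) - 1))
    widths <- as.integer(round(widths))
    images <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      img <- matrix(0.5 + runif(nr * nc, -0.3, 0.3), nr, nc)
      w <- widths[i]
      if (w > 0) {
        c_lo <- floor((nc - w) / 2) + 1L
        img[, c_lo:(c_lo + w - 1L)] <-
          matrix(0.05 + runif(nr * w, 0, 0.02), nr, w)
      }
      images[[i]] <- img
    }
    list(images = images, times_h = (seq_len(n_frames) - 1) * dt_h,
         truth = list(area_px2 = as.numeric(widths) * nr,
                      width_px = widths))
  })
}

#' Generate a differential-expression table with known true positives
#'
#' Emulates a gene-level DE result table (gene_id, log2 fold change,
#' adjusted p-value). True DE genes receive `|log2fc|` drawn from
#' `effect_log2fc_range` (random sign) and `padj` below 0.05; background
#' genes receive small-noise fold changes and `padj` at or above 0.05, so
#' the standard significance filter recovers the truth set exactly.
#'
#' @param n_genes number of genes.
#' @param frac_de fraction of genes that are truly differential, in \[0, 1\].
#' @param effect_log2fc_range range of absolute log2 fold changes for true
#'   DE genes (lower bound >= 1 so effects clear the 2-fold cut).
#' @param seed integer RNG seed.
#' @return list with `table` (data.frame gene_id/log2fc/padj) and `truth`
#'   (character vectors `de_genes`, `up`, `down`).
#' @export
gen_de_table <- function(n_genes, frac_de = 0.1,
                         effect_log2fc_range = c(1, 4), seed = 1L) {
  stopifnot(n_genes >= 1, frac_de >= 0, frac_de <= 1,
            length(effect_log2fc_range) == 2, effect_log2fc_range[1] >= 1)
  with_seed(seed, {
    ids <- sprintf("gene%05d", seq_len(n_genes))
    n_de <- round(n_genes * frac_de)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    lfc <- rnorm(n_genes, 0, 0.25)
    padj <- runif(n_genes, 0.05, 1)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    lfc[de_idx] <- sgn * runif(n_de, effect_log2fc_range[1],
                               effect_log2fc_range[2])
    padj[de_idx] <- runif(n_de, 0, 0.049)
    tab <- data.frame(gene_id = ids, log2fc = lfc, padj = padj,
                      stringsAsFactors = FALSE)
    list(table = tab,
         truth = list(de_genes = ids[de_idx],
                      up = ids[de_idx][sgn > 0],
                      down = ids[de_idx][sgn < 0]))
  })
}
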