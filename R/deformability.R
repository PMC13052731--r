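# Nuclear aspect ratio (NAR) and strain-series tracking.
#
# NAR is the axis ratio of the ellipse with the same second central moments
# as the nucleus mask. Under applied substrate strain a stiffer nucleus
# resists elongation (NAR stays near its rest value); a softened nucleus
# follows the substrate and its NAR grows with strain.

#' Nuclear aspect ratio of a mask
#'
#' Ratio of major to minor axis of the moment-equivalent ellipse. Second
#' central moments of the mask pixels are computed with the 1/12 per-pixel
#' variance correction (a pixel is a unit square, not a point), which makes
#' small rasterized shapes track their continuous counterparts closely.
#' A numeric mask is treated as per-pixel coverage weights (anti-aliased
#' rasterization), which recovers subpixel boundary information that a
#' hard binary mask discards. Always >= 1 by construction; rotation
#' invariant.
#'
#' @param mask logical matrix (or numeric coverage weights in \[0, 1\])
#'   with total weight at least 5 px.
#' @return unitless NAR, with the moment-ellipse semi-axes (`semi_major`,
#'   `semi_minor`, in pixels) and orientation attached as attributes.
#' @export
nar <- function(mask) {
  if (is.logical(mask)) mask <- mask + 0
  stopifnot(is.numeric(mask), length(dim(mask)) == 2, all(mask >= 0))
  idx <- which(mask > 0, arr.ind = TRUE)
  w <- mask[mask > 0]
  n <- sum(w)
  if (n < 5) stop("mask area below 5 px")
  r <- idx[, 1]; c <- idx[, 2]
  mr <- sum(w * r) / n; mc <- sum(w * c) / n
  # weighted population central moments + unit-square pixel correction
  m20 <- sum(w * (c - mc)^2) / n + 1 / 12   # x = col
  m02 <- sum(w * (r - mr)^2) / n + 1 / 12   # y = row
  m11 <- sum(w * (c - mc) * (r - mr)) / n
  tr <- m20 + m02
  d <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (tr + d) / 2
  l2 <- (tr - d) / 2
  semi_major <- 2 * sqrt(l1)
  semi_minor <- 2 * sqrt(l2)
  # masks thinner than ~2 px carry no usable axis-ratio information
  if (semi_minor < 1) stop("degenerate mask: minor axis below 2 px")
  structure(sqrt(l1 / l2),
            semi_major = semi_major, semi_minor = semi_minor,
            orientation = 0.5 * atan2(2 * m11, m20 - m02))
}

#' Match nuclei between two segmented frames
#'
#' Greedy nearest-centroid matching after compensating the global affine
#' stretch between the frames. The per-axis stretch is estimated from the
#' ratio of centroid-cloud standard deviations (or supplied directly);
#' frame-a centroids are mapped through it before distances are computed.
#' Each object is matched at most once; pairs farther than `max_disp_px`
#' after compensation are dropped.
#'
#' @param frame_a,frame_b `nuclei_field` objects.
#' @param max_disp_px maximum residual displacement for a valid match
#'   (default 15).
#' @param stretch optional c(row, col) global stretch factors from frame a
#'   to frame b; estimated from the centroid clouds when `NULL`.
#' @return data.frame with `label_a`, `label_b`, `dist_px`.
#' @export
match_nuclei <- function(frame_a, frame_b, max_disp_px = 15,
                         stretch = NULL) {
  stopifnot(inherits(frame_a, "nuclei_field"),
            inherits(frame_b, "nuclei_field"))
  ra <- frame_a$regions; rb <- frame_b$regions
  empty <- data.frame(label_a = integer(0), label_b = integer(0),
                      dist_px = numeric(0))
  if (nrow(ra) == 0 || nrow(rb) == 0) return(empty)
  ca <- cbind(ra$centroid_row, ra$centroid_col)
  cb <- cbind(rb$centroid_row, rb$centroid_col)
  mua <- colMeans(ca); mub <- colMeans(cb)
  if (is.null(stretch)) {
    stretch <- c(1, 1)
    if (nrow(ca) >= 3 && nrow(cb) >= 3) {
      sda <- apply(ca, 2, stats::sd); sdb <- apply(cb, 2, stats::sd)
      ok <- sda > 1e-9
      stretch[ok] <- sdb[ok] / sda[ok]
    }
  }
  mapped <- sweep(sweep(ca, 2, mua), 2, stretch, `*`)
  mapped <- sweep(mapped, 2, mub, `+`)
  d <- sqrt(outer(mapped[, 1], cb[, 1], `-`)^2 +
            outer(mapped[, 2], cb[, 2], `-`)^2)
  ord <- order(d)
  used_a <- logical(nrow(ca)); used_b <- logical(nrow(cb))
  out <- vector("list", min(nrow(ca), nrow(cb)))
  m <- 0L
  for (k in ord) {
    if (d[k] > max_disp_px) break
    i <- (k - 1L) %% nrow(ca) + 1L
    j <- (k - 1L) %/% nrow(ca) + 1L
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    m <- m + 1L
    out[[m]] <- data.frame(label_a = ra$label[i], label_b = rb$label[j],
                           dist_px = d[k])
  }
  if (m == 0) return(empty)
  do.call(rbind, out[seq_len(m)])
}

#' Measure a strain series: segment, track and compute NAR per frame
#'
#' Segments every frame, links nuclei across consecutive strain levels with
#' [match_nuclei()], and records NAR per track per strain. Tracks are
#' anchored at strain 0; a nucleus lost at any strain level censors the
#' remainder of its track.
#'
#' @param images list of 2D matrices, one per strain level.
#' @param strains numeric strains, strictly increasing, starting at 0.
#' @param max_disp_px matching tolerance passed to [match_nuclei()].
#' @param ... passed to [segment_nuclei()].
#' @return object of class `strain_series`: list with `strains`, `frames`
#'   (segmented `nuclei_field`s) and `tracks` (data.frame `track_id`,
#'   `strain`, `nar`, `label`).
#' @export
measure_strain_series <- function(images, strains, max_disp_px = 15, ...) {
  stopifnot(length(images) == length(strains), length(strains) >= 1)
  if (strains[1] != 0) stop("first strain level must be 0")
  if (is.unsorted(strains, strictly = TRUE)) {
    stop("strains must be strictly increasing")
  }
  frames <- lapply(images, segment_nuclei, ...)
  nar_of <- function(field, label) {
    tryCatch(as.numeric(nar(region_mask(field, label))),
             error = function(e) NA_real_)
  }
  f0 <- frames[[1]]
  tracks <- data.frame(track_id = f0$regions$label, strain = 0,
                       nar = vapply(f0$regions$label,
                                    function(l) nar_of(f0, l), numeric(1)),
                       label = f0$regions$label)
  cur <- data.frame(track_id = f0$regions$label, label = f0$regions$label)
  if (length(strains) > 1) {
    for (i in 2:length(strains)) {
      pairs <- match_nuclei(frames[[i - 1]], frames[[i]],
                            max_disp_px = max_disp_px)
      nxt <- merge(cur, pairs, by.x = "label", by.y = "label_a")
      if (nrow(nxt) > 0) {
        add <- data.frame(track_id = nxt$track_id, strain = strains[i],
                          nar = vapply(nxt$label_b,
                                       function(l) nar_of(frames[[i]], l),
                                       numeric(1)),
                          label = nxt$label_b)
        tracks <- rbind(tracks, add)
      }
      cur <- data.frame(track_id = nxt$track_id, label = nxt$label_b)
      if (nrow(cur) == 0) break
    }
  }
  tracks <- tracks[!is.na(tracks$nar), ]
  structure(list(strains = strains, frames = frames,
                 tracks = tracks[order(tracks$track_id, tracks$strain), ]),
            class = "strain_series")
}

#' NAR-strain response: per-track slopes and pooled correlation
#'
#' For each tracked nucleus with at least two strain levels, fits an
#' ordinary least-squares slope of NAR against strain. The population
#' response is the Pearson correlation of pooled (strain, dNAR) pairs,
#' where dNAR = NAR(strain) - NAR(0) per track. A flat (zero-variance)
#' response yields correlation 0 with `constant = TRUE` flagged.
#'
#' @param series a `strain_series` from [measure_strain_series()].
#' @return list with `slopes` (data.frame `track_id`, `slope`, `n`),
#'   `pearson_r`, `constant` flag, `n_excluded` (tracks with < 2 points).
#' @export
nar_strain_response <- function(series) {
  stopifnot(inherits(series, "strain_series"))
  tr <- series$tracks
  ids <- unique(tr$track_id)
  per <- lapply(ids, function(id) {
    d <- tr[tr$track_id == id, ]
    if (nrow(d) < 2) return(NULL)
    co <- stats::coef(stats::lm(nar ~ strain, data = d))
    data.frame(track_id = id, slope = unname(co[2]), n = nrow(d))
  })
  n_excl <- sum(vapply(per, is.null, logical(1)))
  if (n_excl > 0) {
    message(n_excl, " track(s) with < 2 strain levels excluded")
  }
  slopes <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(slopes)) {
    slopes <- data.frame(track_id = integer(0), slope = numeric(0),
                         n = integer(0))
  }
  # pooled (strain, dNAR) correlation, dNAR anchored at the strain-0 value
  pooled <- do.call(rbind, lapply(ids, function(id) {
    d <- tr[tr$track_id == id, ]
    base <- d$nar[d$strain == 0]
    if (length(base) != 1 || nrow(d) < 2) return(NULL)
    data.frame(strain = d$strain, dnar = d$nar - base)
  }))
  constant <- FALSE
  if (is.null(pooled) || nrow(pooled) < 3 ||
      stats::sd(pooled$dnar) == 0 || stats::sd(pooled$strain) == 0) {
    r <- 0
    constant <- TRUE
  } else {
    r <- stats::cor(pooled$strain, pooled$dnar)
  }
  list(slopes = slopes, pearson_r = r, constant = constant,
       n_excluded = n_excl)
}
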