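# Shared fixtures and independent oracles, built in code at test time.

# Anti-aliased ellipse mask: per-pixel coverage estimated on an ss x ss
# subpixel grid. Centre at the frame centre; semi-axes (a, b), orientation
# theta measured from the column axis.
rasterize_ellipse <- function(a, b, theta, ss = 4) {
  n <- ceiling(2 * a) + 6
  ctr <- (n + 1) / 2
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss
  cov <- matrix(0, n, n)
  for (or in offs) for (oc in offs) {
    rr <- matrix(seq_len(n) + or, n, n) - ctr
    cc <- t(matrix(seq_len(n) + oc, n, n)) - ctr
    u <- (cc * cos(theta) + rr * sin(theta)) / a
    v <- (-cc * sin(theta) + rr * cos(theta)) / b
    cov <- cov + ((u^2 + v^2) <= 1)
  }
  cov / ss^2
}

# Hard (pixel-centre) ellipse mask.
binary_ellipse <- function(a, b, theta, n = NULL) {
  n <- if (is.null(n)) ceiling(2 * a) + 6 else n
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- t(rr)
  u <- (cc * cos(theta) + rr * sin(theta)) / a
  v <- (-cc * sin(theta) + rr * cos(theta)) / b
  (u^2 + v^2) <= 1
}

# Gaussian blur of a 2D image with reflected padding (independent of the
# package's internal smoothing helpers only in its driver; used to probe
# texture-smoothing behaviour).
blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  p <- img[ri, ci]
  # separable: rows then cols
  tmp <- apply(p, 2, function(col) as.numeric(stats::filter(col, k,
                                                            sides = 2)))
  tmp <- tmp[(r + 1):(r + nr), , drop = FALSE]
  tmp2 <- t(apply(tmp, 1, function(row) as.numeric(stats::filter(row, k,
                                                                 sides = 2))))
  tmp2[, (r + 1):(r + nc), drop = FALSE]
}

# Brute-force CCP oracle: explicit double-loop 3x3 Sobel convolution,
# per-nucleus min-max normalization, fixed fraction-of-attainable-max
# threshold, 1-px eroded interior, mask-area denominator. Shares no code
# with nucmorph::ccp.
ccp_oracle <- function(image, mask, frac = 0.25) {
  stopifnot(sum(mask) > 0)
  v <- image[mask]
  rngv <- range(v)
  imgn <- if (rngv[2] > rngv[1]) (image - rngv[1]) / (rngv[2] - rngv[1])
          else image * 0
  nr <- nrow(imgn); nc <- ncol(imgn)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  refl <- function(i, n) { i <- ifelse(i < 1, 2 - i, i); ifelse(i > n, 2 * n - i, i) }
  n_edge <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    # interior test: all 8 neighbours inside mask and not on image border
    if (r == 1 || r == nr || c == 1 || c == nc) next
    interior <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (!mask[r + dr, c + dc]) interior <- FALSE
    }
    if (!interior) next
    gx <- 0; gy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      val <- imgn[refl(r + dr, nr), refl(c + dc, nc)]
      gx <- gx + kx[dr + 2, dc + 2] * val
      gy <- gy + ky[dr + 2, dc + 2] * val
    }
    if (sqrt(gx^2 + gy^2) > frac * 4 * sqrt(2)) n_edge <- n_edge + 1L
  }
  n_edge / sum(mask)
}

# Textured synthetic nucleus with no background step: intensity dome over
# the whole frame plus sharp foci inside the central mask. Used for
# texture-smoothing properties where a nucleus/background edge would
# confound the statistic.
textured_nucleus <- function(seed = 42, n = 81, mask_r = 20, n_foci = 20) {
  set.seed(seed)
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- t(rr)
  rho2 <- (rr^2 + cc^2) / ((n / 2)^2)
  img <- 0.5 + 0.12 * pmax(0, 1 - rho2)
  for (i in seq_len(n_foci)) {
    fr <- sqrt(runif(1)) * 0.8 * mask_r
    an <- runif(1, 0, 2 * pi)
    img <- img + 0.4 * runif(1, 0.8, 1.2) *
      exp(-((rr - fr * sin(an))^2 + (cc - fr * cos(an))^2) / (2 * 1.2^2))
  }
  list(image = img, mask = (rr^2 + cc^2) <= mask_r^2)
}

# Greedy nearest-neighbour matching of detected cells to truth cells in xy;
# returns truth row index per detected row.
match_cells_to_truth <- function(cells, truth) {
  stopifnot(nrow(cells) == nrow(truth))
  d <- sqrt(outer(cells$x_um, truth$x_um, `-`)^2 +
            outer(cells$y_um, truth$y_um, `-`)^2)
  m <- integer(nrow(cells))
  used <- logical(nrow(truth))
  for (k in order(d)) {
    i <- (k - 1L) %% nrow(cells) + 1L
    j <- (k - 1L) %/% nrow(cells) + 1L
    if (m[i] > 0 || used[j]) next
    m[i] <- j; used[j] <- TRUE
    if (all(m > 0)) break
  }
  m
}
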