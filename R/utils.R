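# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring global RNG state after.
# All generators route randomness through this so identical spec + seed gives
# bit-identical output regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# min-max normalize a numeric vector/array to [0, 1]; constant input -> 0s.
norm01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1]) || r[2] <= r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# Otsu threshold on an arbitrary-scale numeric image. The image is min-max
# scaled to [0,1] first; the returned threshold is on the original scale.
otsu_threshold <- function(img) {
  r <- range(img, finite = TRUE)
  if (r[2] <= r[1]) return(r[1])
  x <- norm01(img)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  th01 <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  r[1] + th01 * (r[2] - r[1])
}

# 2D shift of a matrix by (dr, dc) with edge replication (used for erosion
# and local-neighborhood logic without looping).
shift2 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Binary erosion of a logical matrix by a 3x3 box (8-connected): a pixel
# survives iff all 8 neighbours (and itself) are TRUE. Pixels on the image
# border never survive (outside the frame counts as background).
erode3x3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift2(mask, dr, dc)
  }
  out[c(1, nrow(out)), ] <- FALSE
  out[, c(1, ncol(out))] <- FALSE
  out
}

# Reflect-pad a matrix by `k` pixels on every side.
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci, drop = FALSE]
}

# 3x3 correlation of `img` with kernel `k` (no padding; caller pads).
# Vectorized as a sum of shifted copies; returns matrix of same size with
# the 1-px border undefined (caller discards it).
conv3x3 <- function(img, k) {
  out <- matrix(0, nrow(img), ncol(img))
  for (i in 1:3) for (j in 1:3) {
    out <- out + k[i, j] * shift2(img, 2L - i, 2L - j)
  }
  out
}

# Separable Gaussian smoothing of a 3D array, sigma per axis in voxels.
# Kernel truncated at 3 sigma; edges renormalized (replicate-free).
gauss_smooth3 <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3, length(sigma) == 3)
  sm <- a
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    sm <- conv_axis3(sm, k, ax)
  }
  sm
}

# 1D convolution of a 3D array along axis `ax` with kernel `k` (odd length),
# replicate boundary.
conv_axis3 <- function(a, k, ax) {
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  out <- array(0, d)
  n <- d[ax]
  for (i in seq_along(k)) {
    off <- i - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[i] * switch(ax,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE])
  }
  out
}

# Bilinear sampling of matrix `img` at fractional (row, col) coordinates.
# Out-of-frame samples return `fill`.
bilinear_sample <- function(img, rr, cc, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- as.vector(rr); cc <- as.vector(cc)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # clamp indices so subscripting is legal, then mask
  r0c <- pmin(pmax(r0, 1), nr - 1); c0c <- pmin(pmax(c0, 1), nc - 1)
  i00 <- cbind(r0c, c0c); i10 <- cbind(r0c + 1, c0c)
  i01 <- cbind(r0c, c0c + 1); i11 <- cbind(r0c + 1, c0c + 1)
  v <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
    (1 - fr) * fc * img[i01] + fr * fc * img[i11]
  v[!ok] <- fill
  v
}
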