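test_that("nar recovers analytic axis ratios of rasterized ellipses", {
  # disc: unit ratio within 2%
  disc <- binary_ellipse(20, 20, 0)
  expect_equal(as.numeric(nar(disc)), 1, tolerance = 0.02)
  # 30 x 15 ellipse: ratio 2 within the binary-mask tolerance
  expect_equal(as.numeric(nar(binary_ellipse(30, 15, 0))), 2,
               tolerance = 0.05 / 2)
  # rotation leaves the ratio unchanged within 1%
  n0 <- as.numeric(nar(binary_ellipse(24, 12, 0)))
  n37 <- as.numeric(nar(binary_ellipse(24, 12, 37 * pi / 180)))
  expect_equal(n37, n0, tolerance = 0.01)
  expect_error(nar(matrix(FALSE, 5, 5)), "area")
  thin <- matrix(FALSE, 30, 30); thin[15, 5:25] <- TRUE
  expect_error(nar(thin), "degenerate")
})

test_that("nar agrees with the covariance-eigenvalue oracle on random ellipses", {
  set.seed(17)
  for (i in 1:100) {
    a <- runif(1, 5, 30); b <- runif(1, 5, a); th <- runif(1, 0, pi)
    msk <- binary_ellipse(a, b, th)
    pts <- which(msk, arr.ind = TRUE)
    ev <- eigen(stats::cov(pts) * (nrow(pts) - 1) / nrow(pts),
                symmetric = TRUE, only.values = TRUE)$values
    oracle <- sqrt(ev[1] / ev[2])
    expect_equal(as.numeric(nar(msk)), oracle, tolerance = 0.01)
  }
})

test_that("matching is identity for identical and translated frames", {
  f <- gen_nucleus_field(nucleus_field_spec(n_nuclei = 12, seed = 19,
                                            image_shape = c(300, 300)))
  seg <- segment_nuclei(f$image)
  same <- match_nuclei(seg, seg)
  expect_equal(nrow(same), 12)
  expect_equal(same$label_a, same$label_b)
  # translate by 3 px
  img_t <- matrix(0, 300, 300)
  img_t[4:300, 4:300] <- f$image[1:297, 1:297]
  seg_t <- segment_nuclei(img_t)
  pairs <- match_nuclei(seg, seg_t, max_disp_px = 10)
  expect_equal(nrow(pairs), 12)
  # displacement-only motion: matching is symmetric in its arguments
  rev_pairs <- match_nuclei(seg_t, seg, max_disp_px = 10)
  expect_equal(pairs[order(pairs$label_a), c("label_a", "label_b")],
               rev_pairs[order(rev_pairs$label_b), c("label_b", "label_a")],
               ignore_attr = TRUE)
  # empty frames pair to nothing
  blank <- segment_nuclei(matrix(0, 50, 50))
  expect_equal(nrow(match_nuclei(seg, blank)), 0)
})

test_that("tracking follows the generator's truth correspondence", {
  ser <- gen_strain_series(
    nucleus_field_spec(image_shape = c(300, 300), n_nuclei = 8,
                       radius_px = 12, condensation = 0.6, seed = 5),
    c(0, 0.05, 0.10, 0.15))
  ss <- measure_strain_series(ser$images, ser$strains)
  # every nucleus tracked through every strain level
  expect_equal(length(unique(ss$tracks$track_id)), 8)
  expect_true(all(table(ss$tracks$track_id) == 4))
  # matched objects sit near the truth's strained centroid (id k maps to
  # truth nucleus k up to segmentation label permutation, checked by
  # distance to the nearest truth centroid being the SAME truth index
  # across frames)
  for (id in unique(ss$tracks$track_id)) {
    tr <- ss$tracks[ss$tracks$track_id == id, ]
    truth_idx <- vapply(seq_len(nrow(tr)), function(j) {
      i <- which(ser$strains == tr$strain[j])
      reg <- ss$frames[[i]]$regions
      cen <- reg[reg$label == tr$label[j], c("centroid_row", "centroid_col")]
      tc <- ser$truth$frames[[i]]$centroids
      which.min((tc[, "row"] - cen$centroid_row)^2 +
                (tc[, "col"] - cen$centroid_col)^2)
    }, integer(1))
    expect_equal(length(unique(truth_idx)), 1)
  }
})

test_that("measured NAR tracks the affine ground truth across strain", {
  ser <- gen_strain_series(
    nucleus_field_spec(image_shape = c(400, 400), n_nuclei = 10,
                       radius_px = 20, nar_range = c(1, 1),
                       condensation = 0.6, seed = 5),
    seq(0, 0.15, by = 0.03), transverse = "none")
  ss <- measure_strain_series(ser$images, ser$strains)
  resp <- nar_strain_response(ss)
  # stretched circles, no contraction: NAR at 15% is 1.15 (pixelation 0.03)
  top <- ss$tracks[ss$tracks$strain == 0.15, ]
  expect_true(all(abs(top$nar - 1.15) <= 0.03))
  # per-track OLS slopes near 1, pooled correlation essentially perfect
  expect_equal(mean(resp$slopes$slope), 1, tolerance = 0.1)
  expect_gte(resp$pearson_r, 0.99)
  expect_false(resp$constant)
})

test_that("rigid translation yields zero slopes and a flagged correlation", {
  f <- gen_nucleus_field(nucleus_field_spec(n_nuclei = 6, seed = 23,
                                            image_shape = c(250, 250)))
  imgs <- list(f$image, f$image, f$image)
  ss <- measure_strain_series(imgs, c(0, 0.05, 0.10))
  resp <- nar_strain_response(ss)
  expect_true(all(abs(resp$slopes$slope) < 1e-9))
  expect_equal(resp$pearson_r, 0)
  expect_true(resp$constant)
})
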