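test_that("interface detection finds a step tissue profile", {
  # tissue occupies planes 11+ at 2 um steps: first occupied z is 20 um
  arr <- array(0, c(40, 40, 16))
  set.seed(2)
  for (z in 11:16) arr[, , z] <- matrix(runif(1600, 0.5, 1), 40, 40)
  zi <- detect_interface(arr, 2)
  expect_lt(abs(as.numeric(zi) - 20), 2 + 1e-9)  # within one z-step
  expect_error(detect_interface(array(0, c(10, 10, 5)), 2), "constant")
  expect_error(detect_interface(arr[, , 1:2, drop = FALSE], 2), "planes")
  expect_error(detect_interface(arr, 0), "z_step")
})

test_that("detected interface matches generator truth within one z-step", {
  st <- gen_migration_stack(n_cells = 40, n_embedded = 12, seed = 11)
  zi <- detect_interface(st$tissue_channel, st$z_step_um)
  expect_lt(abs(as.numeric(zi) - st$interface_z_um), st$z_step_um + 1e-9)
})

test_that("cell depths and embedded flags are recovered from the stack", {
  st <- gen_migration_stack(n_cells = 40, n_embedded = 12, seed = 11)
  cells <- score_cells(st)
  expect_equal(nrow(cells), 40)
  m <- match_cells_to_truth(cells, st$truth)
  rmse <- sqrt(mean((cells$depth_um - st$truth$depth_um[m])^2))
  expect_lt(rmse, st$z_step_um)
  expect_equal(cells$embedded, st$truth$embedded[m])
  expect_equal(percent_migrated(cells), 30)
})

test_that("flipping the stack in z negates measured depths", {
  st <- gen_migration_stack(n_cells = 10, n_embedded = 5, seed = 4)
  nz <- dim(st$cell_channel)[3]
  flip <- st
  flip$cell_channel <- st$cell_channel[, , nz:1]
  flip$tissue_channel <- st$tissue_channel[, , nz:1]
  a <- score_cells(st)
  b <- score_cells(flip)
  ma <- match_cells_to_truth(a, st$truth)
  tr_flip <- st$truth
  tr_flip$z_um <- (nz - 1) * st$z_step_um - st$truth$z_um
  mb <- match_cells_to_truth(b, tr_flip)
  da <- a$depth_um[order(ma)]
  db <- b$depth_um[order(mb)]
  # negation holds up to sub-voxel centroid residuals
  expect_lt(max(abs(db + da)), st$z_step_um)
})

test_that("percent migrated is order- and translation-invariant", {
  st <- gen_migration_stack(n_cells = 20, n_embedded = 8, seed = 6)
  cells <- score_cells(st)
  expect_equal(percent_migrated(cells), 40)
  expect_equal(percent_migrated(cells[sample(nrow(cells)), ]),
               percent_migrated(cells))
  # translate the whole stack in xy by 5 px
  sh <- st
  d <- dim(st$cell_channel)
  sh$cell_channel <- array(0, d); sh$tissue_channel <- st$tissue_channel
  sh$cell_channel[6:d[1], 6:d[2], ] <- st$cell_channel[1:(d[1] - 5), 1:(d[2] - 5), ]
  expect_equal(percent_migrated(score_cells(sh)), percent_migrated(cells))
  expect_error(percent_migrated(cells[0, ]), "no cells")
})

test_that("a depth-distribution shift is recovered in the mean depth", {
  delta <- 6
  base <- list(name = "normal", mean_um = 10, sd_um = 3)
  shifted <- list(name = "normal", mean_um = 10 + delta, sd_um = 3)
  mean_det <- function(dist, seeds) {
    mean(vapply(seeds, function(s) {
      st <- gen_migration_stack(n_cells = 20, depth_distribution = dist,
                                seed = s)
      mean(score_cells(st)$depth_um)
    }, numeric(1)))
  }
  d_hat <- mean_det(shifted, 1:5) - mean_det(base, 1:5)
  expect_lt(abs(d_hat - delta), 2)  # within one z-step
})

test_that("cumulative frequency curves are normalized and nondecreasing", {
  cf <- cumulative_frequency(c(0, 10, 20, 30), bin_edges = c(15, 35))
  expect_equal(cf$cum_pct[cf$depth_um == 15], 50)
  expect_equal(cf$cum_pct[nrow(cf)], 100)
  one <- cumulative_frequency(12.5)
  expect_equal(one$depth_um, 12.5)
  expect_equal(one$cum_pct, 100)
  set.seed(5)
  for (i in 1:10) {
    d <- rnorm(sample(3:40, 1), 10, 8)
    cc <- cumulative_frequency(d, bin_edges = c(0, 5, 10))
    expect_true(all(diff(cc$cum_pct) >= 0))
    expect_equal(cc$cum_pct[nrow(cc)], 100)
  }
  expect_error(cumulative_frequency(numeric(0)), "no depths")
})

test_that("scratch area tracks the generated void and its symmetries", {
  sc <- gen_scratch_series(frame_shape = c(500, 600), initial_width_px = 100,
                           closure_px_per_frame = 25, n_frames = 5, seed = 3)
  a0 <- as.numeric(scratch_area(sc$images[[1]]))
  expect_equal(a0, 50000, tolerance = 0.02)
  # 180-degree rotation leaves the measured area unchanged
  rot <- sc$images[[1]][500:1, 600:1]
  expect_equal(as.numeric(scratch_area(rot)), a0)
  # fully confluent frame: no void
  set.seed(10)
  conf <- matrix(0.5 + runif(500 * 600, -0.3, 0.3), 500)
  aconf <- scratch_area(conf)
  expect_equal(as.numeric(aconf), 0)
  expect_false(attr(aconf, "found"))
})

test_that("closure rate matches arithmetic and generator truth", {
  expect_equal(as.numeric(closure_rate(c(0, 4, 8, 12), c(100, 75, 50, 25))),
               -6.25)
  expect_equal(as.numeric(closure_rate(c(0, 4, 8), c(40, 40, 40))), 0)
  sc <- gen_scratch_series(frame_shape = c(500, 600), initial_width_px = 100,
                           closure_px_per_frame = 25, n_frames = 5, seed = 3)
  meas <- vapply(sc$images, function(i) as.numeric(scratch_area(i)),
                 numeric(1))
  slope <- as.numeric(closure_rate(sc$times_h, meas))
  truth_slope <- -25 * 500 / 4
  expect_equal(slope, truth_slope, tolerance = 0.05)
  expect_error(closure_rate(c(0, 4), c(0, 0)), "fewer than 2")
})
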