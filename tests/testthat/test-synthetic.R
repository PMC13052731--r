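test_that("nucleus field generation is deterministic and truth-complete", {
  sp <- nucleus_field_spec(n_nuclei = 12, seed = 7, condensation = 0.8)
  f1 <- gen_nucleus_field(sp)
  f2 <- gen_nucleus_field(sp)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$truth$label_map, f2$truth$label_map)
  expect_equal(f1$truth$n, 12)
  expect_equal(nrow(f1$truth$centroids), 12)
  expect_equal(length(f1$truth$true_nar), 12)
  # every label present exactly once, disjoint by construction of label map
  expect_setequal(setdiff(unique(as.vector(f1$truth$label_map)), 0L), 1:12)
  # nuclei fully inside the frame: no foreground on the border
  lm <- f1$truth$label_map
  expect_true(all(lm[c(1, nrow(lm)), ] == 0) && all(lm[, c(1, ncol(lm))] == 0))
})

test_that("empty field and placement failure behave as specified", {
  f <- gen_nucleus_field(nucleus_field_spec(n_nuclei = 0, seed = 1))
  expect_equal(f$truth$n, 0)
  expect_true(all(f$image == 0))
  expect_equal(nrow(f$truth$centroids), 0)
  expect_error(
    gen_nucleus_field(nucleus_field_spec(image_shape = c(64, 64),
                                         n_nuclei = 40, radius_px = 10,
                                         seed = 1)),
    "placement|too small")
})

test_that("condensation monotonically controls within-nucleus variance", {
  knobs <- c(0, 0.25, 0.5, 0.75, 1)
  vs <- vapply(knobs, function(cd) {
    f <- gen_nucleus_field(nucleus_field_spec(n_nuclei = 25, seed = 7,
                                              condensation = cd))
    mean(vapply(1:25, function(k) var(f$image[f$truth$label_map == k]),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
  # fully decondensed interior is near-uniform (only the faint dome left)
  expect_lt(vs[1], 0.05 * vs[5])
})

test_that("strain series geometry matches plane-strain affine truth", {
  sp <- nucleus_field_spec(image_shape = c(200, 200), n_nuclei = 5,
                           radius_px = 14, nar_range = c(1, 1),
                           condensation = 0.6, seed = 5)
  # single zero strain: identity map reproduces the base frame
  s0 <- gen_strain_series(sp, 0)
  expect_identical(s0$images[[1]], gen_nucleus_field(sp)$image)
  # area-preserving: circle at 15% -> true NAR (1.15)^2
  sa <- gen_strain_series(sp, c(0, 0.15), transverse = "area")
  expect_equal(sa$truth$frames[[2]]$true_nar, rep(1.15^2, 5),
               tolerance = 1e-9)
  # no transverse contraction: true NAR 1.15
  sn <- gen_strain_series(sp, c(0, 0.15), transverse = "none")
  expect_equal(sn$truth$frames[[2]]$true_nar, rep(1.15, 5),
               tolerance = 1e-9)
  expect_error(gen_strain_series(sp, c(0, -0.05)), "negative")
  expect_error(gen_strain_series(sp, c(0.03, 0.06)), "first strain")
})

test_that("migration stack truth encodes depth and the embedding rule", {
  # all cells exactly at the interface: none embedded
  st0 <- gen_migration_stack(n_cells = 5, depths_um = rep(0, 5), seed = 2)
  expect_false(any(st0$truth$embedded))
  # a cell 20 um deep with 5 um blob radius is fully inside the tissue
  st1 <- gen_migration_stack(n_cells = 1, depths_um = 20, seed = 2)
  expect_true(all(st1$truth$embedded))
  expect_equal(st1$truth$depth_um, 20)
  # forced construction: 12 of 40 embedded -> truth percent 30
  st2 <- gen_migration_stack(n_cells = 40, n_embedded = 12, seed = 11)
  expect_equal(100 * mean(st2$truth$embedded), 30)
  # determinism and precondition failures
  st3 <- gen_migration_stack(n_cells = 40, n_embedded = 12, seed = 11)
  expect_identical(st2$cell_channel, st3$cell_channel)
  expect_error(gen_migration_stack(5, z_step_um = 0), "z_step")
})

test_that("scratch series narrows linearly with exact truth areas", {
  sc <- gen_scratch_series(frame_shape = c(500, 600), initial_width_px = 100,
                           closure_px_per_frame = 25, n_frames = 5, seed = 1)
  expect_equal(sc$truth$area_px2, c(50000, 37500, 25000, 12500, 0))
  expect_equal(sc$times_h, c(0, 4, 8, 12, 16))
  # zero closure: constant areas
  sc0 <- gen_scratch_series(initial_width_px = 80, closure_px_per_frame = 0,
                            n_frames = 3, seed = 1)
  expect_equal(length(unique(sc0$truth$area_px2)), 1)
  expect_error(gen_scratch_series(frame_shape = c(100, 50),
                                  initial_width_px = 60, seed = 1),
               "width")
})

test_that("DE table generator plants a recoverable truth set", {
  g <- gen_de_table(1000, frac_de = 0.1, seed = 3)
  expect_equal(length(g$truth$de_genes), 100)
  expect_true(all(abs(g$table$log2fc[g$table$gene_id %in% g$truth$de_genes]) >= 1))
  expect_true(all(g$table$padj[g$table$gene_id %in% g$truth$de_genes] < 0.05))
  expect_true(all(g$table$padj[!g$table$gene_id %in% g$truth$de_genes] >= 0.05))
  g0 <- gen_de_table(500, frac_de = 0, seed = 4)
  expect_length(g0$truth$de_genes, 0)
})

test_that("simulated outputs round-trip through TIFF and JSON sidecars", {
  dir <- withr::local_tempdir()
  f <- gen_nucleus_field(nucleus_field_spec(n_nuclei = 4, seed = 9))
  sc <- write_image_tiff(f$image, file.path(dir, "field.tif"))
  back <- read_image_tiff(file.path(dir, "field.tif")) * sc
  expect_equal(dim(back), dim(f$image))
  expect_equal(max(abs(back - f$image)), 0, tolerance = 1e-6)
  st <- gen_migration_stack(n_cells = 3, seed = 5)
  sc2 <- write_stack_tiff(st$cell_channel, file.path(dir, "stack.tif"))
  back2 <- read_image_tiff(file.path(dir, "stack.tif")) * sc2
  expect_equal(dim(back2), dim(st$cell_channel))
  expect_lt(max(abs(back2 - st$cell_channel)), 1e-6)
  tr <- list(depths = st$truth$depth_um, n = nrow(st$truth))
  write_truth_json(tr, file.path(dir, "stack.truth.json"))
  back_tr <- read_truth_json(file.path(dir, "stack.truth.json"))
  expect_equal(back_tr$depths, st$truth$depth_um)
  g <- gen_de_table(50, 0.2, seed = 6)
  write_de_table(g$table, file.path(dir, "de.tsv"))
  expect_equal(read_de_table(file.path(dir, "de.tsv")), g$table)
})
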