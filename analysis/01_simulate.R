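#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study conditions every later stage
# consumes — DAPI nucleus fields for the chromatin readouts, a strain
# series for nuclear deformability, two-channel migration z-stacks, a
# scratch-wound time series, and DE result tables. Images go to
# results/simulated/ as float TIFFs with JSON truth sidecars.

suppressMessages(library(nucmorph))
seed <- 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## DAPI fields: vehicle control (condensed) and HDAC-inhibited (decondensed)
for (cond in c(ctrl = 1.0, tsa = 0.0)) {
  nm <- if (cond == 1.0) "ctrl" else "tsa"
  f <- gen_nucleus_field(nucleus_field_spec(n_nuclei = 25, seed = seed,
                                            condensation = cond))
  sc <- write_image_tiff(f$image, file.path(out, paste0("dapi_", nm, ".tif")))
  write_truth_json(list(scale = sc, n = f$truth$n,
                        centroids = f$truth$centroids,
                        true_nar = f$truth$true_nar,
                        condensation = cond),
                   file.path(out, paste0("dapi_", nm, ".truth.json")))
}
message("wrote condensed + decondensed DAPI fields (25 nuclei each)")

## Strain series, 0-15% grip-to-grip in 3% steps, stretch along columns
strains <- c(0, 0.03, 0.06, 0.09, 0.12, 0.15)
ser <- gen_strain_series(
  nucleus_field_spec(image_shape = c(400, 400), n_nuclei = 10,
                     radius_px = 20, nar_range = c(1, 1),
                     condensation = 0.6, seed = seed),
  strains, transverse = "none")
sc <- write_image_tiff(ser$images, file.path(out, "strain_series.tif"))
write_truth_json(list(scale = sc, strains = strains,
                      true_nar = lapply(ser$truth$frames, `[[`, "true_nar")),
                 file.path(out, "strain_series.truth.json"))
message("wrote strain series at ", paste(100 * strains, collapse = "/"),
        "% strain")

## Migration z-stacks: control (few embedded) vs treated (many embedded)
for (grp in c("ctrl", "tsa")) {
  n_emb <- if (grp == "ctrl") 4L else 12L
  st <- gen_migration_stack(n_cells = 40, n_embedded = n_emb,
                            seed = seed + (grp == "tsa"))
  sc <- write_stack_tiff(st$cell_channel,
                         file.path(out, paste0("stack_", grp, "_cells.tif")))
  st_sc <- write_stack_tiff(st$tissue_channel,
                            file.path(out, paste0("stack_", grp,
                                                  "_tissue.tif")))
  write_truth_json(list(cell_scale = sc, tissue_scale = st_sc,
                        z_step_um = st$z_step_um,
                        pixel_size_um = st$pixel_size_um,
                        blob_radius_um = st$blob_radius_um,
                        interface_z_um = st$interface_z_um,
                        cells = st$truth),
                   file.path(out, paste0("stack_", grp, ".truth.json")))
}
message("wrote migration stacks (control: 4/40 embedded, treated: 12/40)")

## Scratch-wound series imaged every 4 h
scr <- gen_scratch_series(frame_shape = c(500, 600), initial_width_px = 100,
                          closure_px_per_frame = 25, n_frames = 5,
                          seed = seed)
sc <- write_image_tiff(scr$images, file.path(out, "scratch_series.tif"))
write_truth_json(list(scale = sc, times_h = scr$times_h,
                      area_px2 = scr$truth$area_px2),
                 file.path(out, "scratch_series.truth.json"))
message("wrote scratch series, true areas ",
        paste(scr$truth$area_px2, collapse = ", "), " px^2")

## DE tables: treatment day 0 vs control, and a noisy replicate pair
g <- gen_de_table(1000, frac_de = 0.1, seed = seed)
write_de_table(g$table, file.path(out, "de_day0.tsv"))
write_truth_json(g$truth, file.path(out, "de_day0.truth.json"))
set.seed(seed + 100)
rep_tab <- g$table
rep_tab$log2fc <- rep_tab$log2fc + rnorm(nrow(rep_tab), 0, 0.3)
write_de_table(rep_tab, file.path(out, "de_day0_replicate.tsv"))
message("wrote DE tables (1000 genes, 100 true effects)")
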