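#!/usr/bin/env Rscript
# Stage 6: assemble the deterministic report bundle from the stage tables.

suppressMessages(library(nucmorph))

stages <- list(
  ccp = read.csv("results/ccp.csv"),
  nar_tracks = read.csv("results/nar_tracks.csv"),
  migration_cells = read.csv("results/migration_cells.csv"),
  scratch = read.csv("results/scratch.csv"),
  de_counts = read.csv("results/de_counts.csv"),
  summary = list(
    ccp_pct_change_mean = mean(read.csv("results/ccp.csv")$pct_change[
      read.csv("results/ccp.csv")$group == "tsa"]),
    percent_migrated_tsa = 100 * mean(read.csv(
      "results/migration_cells.csv")$embedded[
        read.csv("results/migration_cells.csv")$group == "tsa"]),
    de_correlation_r = read.csv("results/de_correlation.csv")$pearson_r))

build_report(stages, dir = "results/report", config = list(seed = 1L))
message("wrote results/report/report.json and per-metric CSVs")
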