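#!/usr/bin/env Rscript
# Stage 2: chromatin condensation. Segments the simulated DAPI fields,
# computes the CCP per nucleus, expresses treated nuclei as a percent
# change against the vehicle-control mean, and compares the groups.

suppressMessages(library(nucmorph))
sim <- "results/simulated"
dir.create("results", showWarnings = FALSE)

load_field <- function(nm) {
  tr <- read_truth_json(file.path(sim, paste0("dapi_", nm, ".truth.json")))
  read_image_tiff(file.path(sim, paste0("dapi_", nm, ".tif"))) * tr$scale
}
ccp_of <- function(img) {
  seg <- segment_nuclei(img)
  vapply(seg$regions$label, function(l) as.numeric(ccp(img, region_mask(seg, l))),
         numeric(1))
}
ccp_ctrl <- ccp_of(load_field("ctrl"))
ccp_tsa <- ccp_of(load_field("tsa"))
res <- ccp_pct_change(treated = ccp_tsa, control = ccp_ctrl)

message(sprintf("control mean CCP %.4f (n=%d); decondensed mean CCP %.4f",
                mean(ccp_ctrl), length(ccp_ctrl), mean(ccp_tsa)))
message(sprintf("mean %% change vs control: %.1f%%", mean(res$pct_change)))

cmp <- compare_groups(list(ctrl = ccp_ctrl, tsa = ccp_tsa))
message(sprintf("t-test: t = %.2f, p = %.3g%s", cmp$statistic, cmp$p_value,
                if (cmp$significant) " (significant)" else ""))

write.csv(rbind(
  data.frame(group = "ctrl", nucleus = seq_along(ccp_ctrl), ccp = ccp_ctrl,
             pct_change = 100 * (ccp_ctrl - mean(ccp_ctrl)) / mean(ccp_ctrl)),
  data.frame(group = "tsa", nucleus = seq_along(ccp_tsa), ccp = ccp_tsa,
             pct_change = res$pct_change)),
  "results/ccp.csv", row.names = FALSE)
message("wrote results/ccp.csv")
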