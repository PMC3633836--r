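#!/usr/bin/env Rscript
# Generate the synthetic study datasets: brightfield spheroid micrographs,
# a stained cross-section, growth time series for a control and a treated
# arm, a dose-response plate, clonogenic counts, and a release profile.
# Ground truth for every dataset goes to a JSON sidecar.

suppressMessages(library(spherokit))

seed <- 20260925L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating brightfield micrographs (6 spheroids, 300-550 um) ...")
diam <- seq(300, 550, length.out = 6)
truth_vol <- lapply(seq_along(diam), function(i) {
  g <- gen_brightfield_spheroid(diam[i], um_per_px = 1.25,
                                image_size_px = 512L, noise_sd = 3,
                                seed = seed + i)
  write_pixel_image(g$image, file.path(out, sprintf("spheroid_%02d.tif", i)))
  g$truth$params[c("diameter_um", "area_um2", "volume_um3")]
})
names(truth_vol) <- sprintf("spheroid_%02d", seq_along(diam))

message("Simulating a Ki67-like section (proliferation rim) ...")
rim <- function(f) 0.05 + 0.9 * (f <= 1 / 3)
sec <- gen_stained_section(150, depth_profile = rim, seed = seed + 101L)
write_pixel_image(sec$image, file.path(out, "section_rim.tif"))
write_pixel_image((sec$mask$mask) * 255, file.path(out, "section_mask.tif"))

message("Simulating growth series (control + treated, n = 6, 10 timepoints) ...")
ctrl <- gen_growth_series(4.2e6, 0.9, 0.25, days = seq(0, 14, length.out = 10),
                          n_replicates = 6, cv = 0.05, arm = "control",
                          seed = seed + 201L)
trt <- gen_growth_series(4.2e6, 0.9 * 0.35, 0.25,
                         days = seq(0, 14, length.out = 10),
                         n_replicates = 6, cv = 0.05, arm = "treated",
                         seed = seed + 202L)
write.csv(rbind(ctrl$data, trt$data), file.path(out, "growth.csv"),
          row.names = FALSE)

message("Simulating an APH dose-response plate (9 concentrations x 3) ...")
plate <- gen_dose_response(ic50 = 10, hill_slope = 1, bottom = 5,
                           concentrations = 10^seq(-2, 3, length.out = 9),
                           n_replicates = 3, noise_sd = 0.02,
                           seed = seed + 301L)
write.csv(plate$data, file.path(out, "plate.csv"), row.names = FALSE)

message("Simulating clonogenic counts and a release profile ...")
clono <- rbind(
  gen_clonogenic(1000, 0.8, 1, "untreated", seed = seed + 401L)$record,
  gen_clonogenic(1000, 0.8, 0.25, "treated_20ng", seed = seed + 402L)$record)
write.csv(clono, file.path(out, "clonogenic.csv"), row.names = FALSE)

rel <- gen_release(k = log(2) / 6, f_inf = 1,
                   times = c(0, 1, 2, 4, 6, 8, 12, 24),
                   noise_sd = 0.01, seed = seed + 501L)
write.csv(rel$data, file.path(out, "release.csv"), row.names = FALSE)

truth <- list(
  seed = seed,
  volumetry = truth_vol,
  section = sec$truth$params[c("radius_px", "threshold", "region_pos_sums",
                               "total_pos_sum")],
  growth = list(control = ctrl$truth$params[c("v0", "alpha", "beta",
                                              "plateau")],
                treated = trt$truth$params[c("v0", "alpha", "beta",
                                             "plateau")]),
  dose_response = plate$truth$params[c("ic50", "hill_slope", "bottom")],
  clonogenic = list(plating_efficiency = 0.8, sf_true = 0.25),
  release = rel$truth$params[c("k", "f_inf", "half_life_h")])
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)
message("Done: synthetic datasets and truth.json written to ", out)
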