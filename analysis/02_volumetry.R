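#!/usr/bin/env Rscript
# Automated spheroid volumetry: segment each brightfield micrograph by
# automated thresholding, measure calibrated area, equivalent diameter and
# sphere volume, and validate the automated volumes against ground truth.

suppressMessages(library(spherokit))

data_dir <- "results/data"
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"),
                             simplifyVector = TRUE)
images <- sort(list.files(data_dir, pattern = "^spheroid_.*\\.tif$",
                          full.names = TRUE))
stopifnot(length(images) > 0)

rows <- do.call(rbind, lapply(images, function(p) {
  img <- read_pixel_image(p, um_per_px = 1.25)
  mk <- segment_spheroid(img)
  m <- measure_spheroid(mk, 1.25)
  cbind(data.frame(image = basename(p)), m)
}))
rows$true_diameter_um <- unlist(lapply(truth$volumetry, `[[`, "diameter_um"))
rows$true_volume_um3 <- unlist(lapply(truth$volumetry, `[[`, "volume_um3"))
rows$diameter_error_pct <- 100 *
  abs(rows$equivalent_diameter_um - rows$true_diameter_um) /
  rows$true_diameter_um

dir.create("results", showWarnings = FALSE)
write.csv(rows, "results/morphometry.csv", row.names = FALSE)

fit <- validate_against_manual(rows$volume_um3, rows$true_volume_um3)
message(sprintf(
  "Measured %d spheroids: max diameter error %.2f%%; auto-vs-truth volume regression slope %.4f, R^2 %.6f",
  nrow(rows), max(rows$diameter_error_pct), fit$slope, fit$r_squared))
jsonlite::write_json(
  list(n = nrow(rows), max_diameter_error_pct = max(rows$diameter_error_pct),
       regression = fit),
  "results/volumetry_validation.json", auto_unbox = TRUE, digits = NA)
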