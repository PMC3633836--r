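#!/usr/bin/env Rscript
# Clonogenic survival statistics (plating efficiency, surviving fraction)
# and drug-release summarization (cumulative fraction released by 12 h).

suppressMessages(library(spherokit))

clono <- read_clonogenic_table("results/data/clonogenic.csv")
truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)

ctrl <- clono[clono$condition == "untreated", ]
trt <- clono[clono$condition != "untreated", ]
pe <- plating_efficiency(ctrl$colonies, ctrl$cells_plated)
sf <- surviving_fraction(trt$colonies, trt$cells_plated, pe)
out <- rbind(cbind(ctrl, plating_efficiency = pe, surviving_fraction = 1),
             cbind(trt, plating_efficiency = pe, surviving_fraction = sf))
write.csv(out, "results/clonogenic_sf.csv", row.names = FALSE)
message(sprintf(
  "Clonogenic: PE = %.3f (truth %.2f); SF(%s) = %.3f (truth %.2f)",
  pe, truth$clonogenic$plating_efficiency, trt$condition, sf,
  truth$clonogenic$sf_true))

rel <- read_release_table("results/data/release.csv")
f12 <- release_fraction_at(rel, 12)
jsonlite::write_json(
  list(fraction_released_12h = f12,
       half_life_h = truth$release$half_life_h,
       clonogenic = list(plating_efficiency = pe, surviving_fraction = sf)),
  "results/assay_summary.json", auto_unbox = TRUE, digits = NA)
message(sprintf(
  "Release: %.0f%% of the drug released by 12 h (first-order, half-life %.1f h)",
  100 * f12, truth$release$half_life_h))
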