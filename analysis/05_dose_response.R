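#!/usr/bin/env Rscript
# Dose-response analysis of the APH plate: normalize treatment wells to the
# control/media anchors and fit the Hill equation; report the absolute IC50
# (or "> max tested" for a resistant plateau).

suppressMessages(library(spherokit))

plate <- read_plate_table("results/data/plate.csv")
truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)

res <- analyze_plate(plate)
fit <- res$fit

write.csv(res$viability, "results/viability.csv", row.names = FALSE)
jsonlite::write_json(
  list(ic50 = fit$ic50, ic50_reached = fit$ic50_reached,
       x50 = fit$x50, hill_slope = fit$hill_slope, bottom = fit$bottom,
       max_tested = fit$max_tested,
       truth = truth$dose_response),
  "results/dose_response_fit.json", auto_unbox = TRUE, digits = NA)

ic_txt <- if (fit$ic50_reached) sprintf("%.3g ng/mL", fit$ic50) else
  sprintf("> %g ng/mL (not reached)", fit$max_tested)
truth_ic50_abs <- truth$dose_response$ic50 *
  (50 / (50 - truth$dose_response$bottom))^(1 / truth$dose_response$hill_slope)
message(sprintf(
  "Hill fit: IC50 = %s, slope = %.2f, bottom = %.1f%% (generating absolute IC50 %.3g ng/mL)",
  ic_txt, fit$hill_slope, fit$bottom, truth_ic50_abs))
if (any(res$viability$out_of_range)) {
  message(sum(res$viability$out_of_range),
          " wells fell outside [0, 100]% viability (retained, flagged).")
}
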