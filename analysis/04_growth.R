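#!/usr/bin/env Rscript
# Gompertz growth modelling and growth-inhibition comparison: fit the
# growth law per arm, summarize replicates (mean +/- SD), and test the
# treated vs control arms at the final timepoint.

suppressMessages(library(spherokit))

growth <- read_growth_table("results/data/growth.csv")
truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)

fits <- lapply(split(growth, growth$arm), function(df) {
  fit_gompertz(df$day, df$volume_um3)
})
summaries <- lapply(split(growth, growth$arm), summarize_growth)
for (arm in names(summaries)) {
  summaries[[arm]]$arm <- arm
}
write.csv(do.call(rbind, summaries), "results/growth_summary.csv",
          row.names = FALSE)

last_day <- max(growth$day)
cmp <- compare_arms(growth[growth$arm == "control", ],
                    growth[growth$arm == "treated", ],
                    timepoint = last_day)

for (arm in names(fits)) {
  f <- fits[[arm]]
  message(sprintf(
    "%s arm: V0 = %.3g um^3, alpha = %.3f/day, beta = %.3f/day, plateau = %.3g um^3 (truth %.3g)",
    arm, f$params["v0"], f$params["alpha"], f$params["beta"], f$plateau,
    truth$growth[[arm]]$plateau))
}
message(sprintf(
  "Day %.0f control vs treated: Welch t = %.2f, p = %.2g %s",
  last_day, cmp$statistic, cmp$p_value,
  if (cmp$p_value < 0.05) "(significant growth inhibition)"
  else "(no significant difference)"))

jsonlite::write_json(
  list(fits = lapply(fits, function(f)
         c(as.list(f$params), plateau = f$plateau,
           plateau_se = f$plateau_se)),
       comparison = c(cmp, list(day = last_day))),
  "results/growth_fit.json", auto_unbox = TRUE, digits = NA)
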