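#!/usr/bin/env Rscript
# Stage 2: reduce the replicated voltage changes to per-subject, per-level
# loss changing rates with propagated repeatability.
#
# Reads the cohorts written by 01_simulate_cohort.R and writes
# results/loss_rates_n50.csv and results/loss_rates_n10.csv.

suppressPackageStartupMessages(library(bela))

for (tag in c("n50", "n10")) {
  meas <- read_measurements_csv(file.path(paste0("results/cohort_", tag),
                                          "measurements.csv"))
  lr <- loss_rate_table(meas)
  out <- paste0("results/loss_rates_", tag, ".csv")
  write.csv(lr, out, row.names = FALSE)
  cat(sprintf(
    "%s: %d subject-levels; m_loss %.3f-%.3f mV/kHz; mean replicate SD %.2f (low) / %.2f (high) mV; mean relative repeatability %.1f %%\n",
    out, nrow(lr), min(lr$m_loss), max(lr$m_loss),
    mean(lr$sigma_L), mean(lr$sigma_H),
    mean(lr$relative_repeatability_pct, na.rm = TRUE)))
}
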