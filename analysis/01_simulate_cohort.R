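#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohorts the downstream stages analyse.
#
# Two cohorts are written under results/:
#   cohort_n50 - 50 subjects, the size at which the correlation structure is
#                stable enough to read off the method's behaviour;
#   cohort_n10 - 10 subjects, the feasibility study's scale, used for the
#                repeatability budget.
# Both use the default study conditions: 103/185 kHz, five replicates at
# each of three abdominal levels, replicate + positioning + ADC noise, and
# the drive gain anchored so the reference anatomy gives 0.6 mV/kHz.

suppressPackageStartupMessages(library(bela))

seed <- 101L

r50 <- simulate_cohort_files("results/cohort_n50", n = 50, seed = seed)
r10 <- simulate_cohort_files("results/cohort_n10", n = 10, seed = seed + 1L)

for (d in c("results/cohort_n50", "results/cohort_n10")) {
  checks <- validate_cohort(d)
  cat(d, ": ", paste(names(checks), checks, sep = "=", collapse = ", "),
      "\n", sep = "")
  stopifnot(all(checks))
}

gt <- r50$cohort$ground_truth
cat(sprintf("n=50 cohort: VF %0.f-%0.f cm^2, noise-free m_loss %.2f-%.2f mV/kHz, WC %.0f-%.0f cm\n",
            min(gt$vf_area), max(gt$vf_area), min(gt$m_loss), max(gt$m_loss),
            min(r50$cohort$subjects$wc_cm), max(r50$cohort$subjects$wc_cm)))
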