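#!/usr/bin/env Rscript
# Generate the synthetic Phase-1 trial: 62 subjects, placebo/10/30/60 mg
# once daily for 120 days plus 120-day follow-up, five endpoints at 20
# visits, log-normal IIV and endpoint-specific residual error.

library(erythrosim)
dir.create("results", showWarnings = FALSE)

dsn <- trial_design()
pop <- population_model()
tr <- generate_trial(dsn, pop, seed = 20260901)

write_obs_table(tr$data, "results/trial_observations.csv")
utils::write.csv(tr$truth, "results/trial_truth.csv", row.names = FALSE)

cat("Synthetic trial:", length(unique(tr$data$ID)), "subjects,",
    nrow(tr$data), "records\n")
for (dose in unique(tr$truth$DOSE)) {
  sel <- tr$truth$DOSE == dose
  cat(sprintf("  %2d mg (n = %2d): median AUC_ss %.1f mg/L*h -> median %d%% inhibition\n",
              dose, sum(sel), stats::median(tr$truth$AUC[sel]),
              round(100 * stats::median(
                inhibition(tr$truth$AUC[sel], 0.6, 16.5)))))
}
mch119 <- sapply(sort(unique(tr$data$DOSE)), function(dose)
  stats::median(tr$data$DV[tr$data$DOSE == dose & tr$data$DVID == 3 &
                             tr$data$TIME == 119]))
cat("  arm-median MCH at day 119 (pg):",
    paste(sprintf("%.1f", mch119), collapse = ", "),
    "(dose-monotone decline)\n")
cat("wrote results/trial_observations.csv and results/trial_truth.csv\n")
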