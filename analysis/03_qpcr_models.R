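#!/usr/bin/env Rscript
# Isoform qPCR quantitation and neuropathology/genotype linear models.
#
# Simulates a full qPCR plate for the 56-sample cohort (all isoform assays
# plus the microglial reference gene), refits the standard curves from the
# plate's own dilution wells, converts Cq to copies, and fits the per-assay
# linear models: log10 target ~ log10 reference + NIARI + SNP doses, with
# standardized betas.

suppressPackageStartupMessages(library(ampliconAEI))
dir.create("results", showWarnings = FALSE)
seed <- 20260930

cfg <- sim_config(depth = 200)   # reads unused here; qPCR noise at default
res <- run_pipeline("results/qpcr_run", seed = seed, config = cfg,
                    cohort_n = 56, stages = c("simulate", "qpcr"))

for (f in res$qpcr) {
  message(sprintf("%-12s adj R^2 = %.3f | beta(log ref) = %+.2f (p = %.2g) | beta(NIARI) = %+.2f (p = %.2g)",
                  f$assay, f$adj_r_squared, f$beta_std$log_itgam,
                  f$p_values$log_itgam, f$beta_std$niari_high,
                  f$p_values$niari_high))
}
message("High-NIARI fold effects are the generator defaults; SNP doses carry no
programmed expression effect, so their p values behave as nulls.")
message("Model fits written to results/qpcr_run/qpcr_model_fits.json")
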