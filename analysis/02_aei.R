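#!/usr/bin/env Rscript
# Allelic expression imbalance from amplicon reads, end to end.
#
# Simulates barcoded cDNA and gDNA amplicon reads for every reporter-SNP
# heterozygote in a 56-sample cohort (with a modest allelic effect tied to
# the rs35349669 risk haplotype), demultiplexes and k-mer-counts the alleles,
# normalizes cDNA ratios to the gDNA controls, and runs both conditional
# genotype-stratified rank-sum tests.

suppressPackageStartupMessages(library(ampliconAEI))
dir.create("results", showWarnings = FALSE)
seed <- 20260930

cfg <- sim_config(depth = 2000, error_rate = 0.005, aei_effect = 1.15)
res <- run_pipeline("results/aei_run", seed = seed, config = cfg,
                    cohort_n = 56,
                    stages = c("simulate", "count", "aei"))

rec <- res$aei$records
inc <- rec[rec$included, ]
message(sprintf("Included %d heterozygotes; gDNA raw ratio mean %.3f (SD %.3f)",
                nrow(inc), mean(inc$raw_ratio_gdna, na.rm = TRUE),
                sd(inc$raw_ratio_gdna, na.rm = TRUE)))
message(sprintf("Normalized cDNA ratio mean %.3f; AEI magnitude median %.4f",
                mean(inc$normalized_ratio), median(inc$aei_magnitude)))

p1 <- res$aei$primary; p2 <- res$aei$reciprocal
message(sprintf("rs35349669 effect (rs10933431-homozygous strata %d vs %d): U = %g, p = %.4g [%s]",
                length(p1$strata$group_homozygous),
                length(p1$strata$group_heterozygous),
                p1$test$u_statistic, p1$test$p_two_sided, p1$test$method))
message(sprintf("rs10933431 effect (rs35349669-homozygous strata): U = %g, p = %.4g [%s]",
                p2$test$u_statistic, p2$test$p_two_sided, p2$test$method))
message("Outputs under results/aei_run/ (counts TSV, AEI TSV, test JSON, manifest)")
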