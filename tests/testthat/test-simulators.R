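# Expression, read, qPCR-plate and CHX time-course simulators.

test_that("null generator settings produce null effects", {
  h <- fixture_haplotype_model()
  co <- simulate_cohort(200, h, seed = 3)
  cfg_null <- sim_config(aei_effect = 1.0,
                         niari_fold = c(itgam = 1, ex10_ex12 = 1, ex2_ex3 = 1,
                                        ex11_ex12 = 1, in14_ex16 = 1,
                                        ex15_ex16 = 1, ex26_present = 1,
                                        d47 = 1))
  ex <- simulate_expression(co, cfg_null, seed = 4)
  het <- is_het(co$genotype_rs1141328)
  expect_true(all(ex$allelic_ratio_true[het] == 1))
  expect_true(all(is.na(ex$allelic_ratio_true[!het])))
  # null NIARI fold: equal expected log copies in the two pathology groups
  hi <- co$niari == "high"
  d <- mean(log10(ex$ex10_ex12[hi])) - mean(log10(ex$ex10_ex12[!hi]))
  sd_d <- sqrt(0.5^2 * (1 / sum(hi) + 1 / sum(!hi)))
  expect_lt(abs(d), 4 * sd_d)
})

test_that("default D47 fraction averages near its configured mean", {
  h <- fixture_haplotype_model()
  co <- simulate_cohort(4000, h, seed = 5)
  ex <- simulate_expression(co, sim_config(), seed = 6)
  expect_lt(abs(mean(ex$d47_fraction) - 0.13), 0.015)
  expect_true(all(ex$d47_fraction >= 0 & ex$d47_fraction <= 1))
  expect_true(all(ex[assay_names()] > 0))
})

test_that("nonpositive fold effects are rejected", {
  expect_error(sim_config(niari_fold = c(itgam = 1, ex10_ex12 = -2)),
               "positive")
})

test_that("read simulator honours genotype, material and determinism", {
  km <- parse_allele_kmer("GCCGGCCC[G/A]GCCGAGG")
  s_hom <- data.frame(sample_id = "H1", genotype_rs1141328 = "GG")
  r <- simulate_amplicon_reads(s_hom, "cDNA", NULL, km, depth = 1000,
                               error_rate = 0, seed = 1)
  ct <- count_alleles(r, km)
  expect_equal(ct$n_allele1, 1000)
  expect_equal(ct$n_allele2 + ct$n_ambiguous + ct$n_unassigned, 0)

  expect_error(simulate_amplicon_reads(s_hom, "plasma", NULL, km, 10),
               "unknown material")

  s_het <- data.frame(sample_id = "H2", genotype_rs1141328 = "GA")
  r1 <- simulate_amplicon_reads(s_het, "gDNA", NULL, km, depth = 500,
                                error_rate = 0.01, seed = 7)
  r2 <- simulate_amplicon_reads(s_het, "gDNA", NULL, km, depth = 500,
                                error_rate = 0.01, seed = 7)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("recovered allele fraction converges at binomial rate", {
  km <- parse_allele_kmer("GCCGGCCC[G/A]GCCGAGG")
  s_het <- data.frame(sample_id = "H3", genotype_rs1141328 = "GA")
  d <- 400
  ok <- vapply(1:30, function(s) {
    r <- simulate_amplicon_reads(s_het, "gDNA", NULL, km, depth = d,
                                 error_rate = 0, seed = s)
    ct <- count_alleles(r, km)
    phat <- ct$n_allele1 / (ct$n_allele1 + ct$n_allele2)
    abs(phat - 0.5) <= 4 * sqrt(0.25 / d)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("error-free simulator output is recovered without assignment loss", {
  km <- parse_allele_kmer("GCCGGCCC[G/A]GCCGAGG")
  s_het <- data.frame(sample_id = "H4", genotype_rs1141328 = "GA")
  es <- data.frame(allelic_ratio_true = 1.6)
  r <- simulate_amplicon_reads(s_het, "cDNA", es, km, depth = 800,
                               error_rate = 0, seed = 21)
  ct <- count_alleles(r, km)
  expect_equal(ct$n_allele1 + ct$n_allele2, 800)  # every read assigned
  expect_equal(ct$n_unassigned + ct$n_ambiguous, 0)
  # the recovered fraction IS the binomial draw made by the simulator
  expect_identical(ct$n_allele1,
                   with_seed_count(21, 800, 1.6 / (1 + 1.6)))
})

test_that("qPCR plate simulator is log-linear and deterministic", {
  es <- data.frame(sample_id = "S1", itgam = 1000, ex10_ex12 = 1)
  curve <- list(slope = -3.3219, intercept = 37)
  p0 <- simulate_qpcr_plate(es, curve, qpcr_sd = 0, seed = 1,
                            assays = c("itgam", "ex10_ex12"))
  # one copy amplifies at the intercept exactly
  expect_equal(p0$cq[p0$well_type == "unknown" & p0$assay == "ex10_ex12"],
               rep(37, 3), tolerance = 1e-12)
  # ten-fold dilution spacing equals |slope|
  std <- p0[p0$well_type == "standard" & p0$assay == "itgam", ]
  std <- std[order(std$copies, std$replicate), ]
  dq <- diff(std$cq[std$replicate == 1])
  expect_equal(dq, rep(-3.3219, 5), tolerance = 1e-12)
  expect_identical(simulate_qpcr_plate(es, curve, qpcr_sd = 0.2, seed = 9),
                   simulate_qpcr_plate(es, curve, qpcr_sd = 0.2, seed = 9))
  expect_error(simulate_qpcr_plate(es, list(slope = 3, intercept = 37)),
               "negative")
  expect_error(simulate_qpcr_plate(data.frame(sample_id = "x", itgam = -1),
                                   curve), "positive")
})

test_that("CHX time course has the designed layout and arithmetic", {
  p <- list(baseline = 0.13, increment = 0.02, timepoints = c(1, 3, 5, 8),
            replicates = 3, noise_sd = 0)
  tc <- simulate_chx_timecourse(p, seed = 1)
  expect_equal(nrow(tc), 24)  # 4 timepoints x 2 arms x 3 replicates
  expect_equal(tc$d47_fraction[tc$treatment == "CHX" & tc$time_h == 8][1],
               0.13 + 0.02 * 8, tolerance = 1e-12)
  expect_true(all(tc$d47_fraction[tc$treatment == "vehicle"] == 0.13))
  p0 <- p; p0$increment <- 0; p0$noise_sd <- 0.01
  tc0 <- simulate_chx_timecourse(p0, seed = 2)
  m <- tapply(tc0$d47_fraction, tc0$treatment, mean)
  expect_lt(abs(m[["CHX"]] - m[["vehicle"]]), 0.02)
  expect_error(simulate_chx_timecourse(list(baseline = 1.4, increment = 0,
                                            timepoints = 1, replicates = 1)),
               "baseline")
})
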