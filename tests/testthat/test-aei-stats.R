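# gDNA normalization, AEI magnitudes, conditional stratification and the
# rank-sum test.

test_that("gDNA normalization behaves in both modes", {
  expect_equal(normalize_to_gdna(1.2, c(1, 1, 1), "cohort_mean"), 1.2)
  expect_equal(normalize_to_gdna(1.05, c(0.99), "cohort_mean"), 1.05 / 0.99)
  r <- c(a = 1.1, b = 0.9)
  expect_equal(unname(normalize_to_gdna(r, r, "paired")), c(1, 1))
  expect_error(normalize_to_gdna(1.2, numeric(0)), "empty")
  expect_error(normalize_to_gdna(-1, 1), "positive")
  expect_error(normalize_to_gdna(c(1, 2), c(1, 2, 3), "paired"), "paired")
})

test_that("AEI magnitude is the absolute deviation from the mean", {
  expect_equal(aei_magnitude(c(0.9, 1.0, 1.1)), c(0.1, 0, 0.1))
  expect_equal(aei_magnitude(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(aei_magnitude(c(0.8, 1.2)), c(0.2, 0.2))
  expect_equal(aei_magnitude(c(0.9, 1.2), anchor = 1), c(0.1, 0.2))
  expect_error(aei_magnitude(1.0), "at least 2")
  # deviations from the cohort mean sum to zero
  set.seed(1)
  r <- exp(rnorm(25, 0, 0.06))
  expect_lt(abs(mean(r - mean(r))), 1e-12)
})

test_that("conditional stratification reproduces the published group sizes", {
  tab <- fixture_genotype_table()
  s1 <- stratify_for_conditional_test(tab, "rs35349669", "rs10933431")
  expect_equal(length(s1$group_homozygous), 17)
  expect_equal(length(s1$group_heterozygous), 21)
  s2 <- stratify_for_conditional_test(tab, "rs10933431", "rs35349669")
  expect_equal(length(s2$group_homozygous), 17)
  expect_equal(length(s2$group_heterozygous), 8)
  # every retained sample is homozygous at the conditioning SNP, groups disjoint
  expect_length(intersect(s1$group_homozygous, s1$group_heterozygous), 0)
  kept <- tab$sample_id %in% c(s1$group_homozygous, s1$group_heterozygous)
  expect_true(all(!is_het(tab$genotype_rs10933431[kept])))
  expect_equal(s1$n_excluded, 61 - 17 - 21)

  empty <- tab[0, ]
  s0 <- stratify_for_conditional_test(empty, "rs35349669", "rs10933431")
  expect_length(s0$group_homozygous, 0)
  expect_equal(s0$n_excluded, 0L)

  bad <- tab; bad$genotype_rs35349669[3] <- "TG"
  expect_error(stratify_for_conditional_test(bad, "rs35349669", "rs10933431"),
               "rows: 3")
})

test_that("rank-sum test gives exact small-sample p values", {
  r1 <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$u_statistic, 0)
  expect_equal(r1$p_two_sided, 0.1)
  expect_equal(r1$method, "exact")
  r2 <- rank_sum_test(c(1, 4), c(2, 3))
  expect_equal(r2$u_statistic, 2)  # = n1 n2 / 2
  expect_equal(r2$p_two_sided, 1.0)
  expect_error(rank_sum_test(c(1, 2), numeric(0)), "nonempty")
})

test_that("exact rank-sum p equals full enumeration on random small samples", {
  set.seed(11)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    if (i %% 2 == 0) {  # with ties
      x <- sample(1:4, n1, replace = TRUE)
      y <- sample(1:4, n2, replace = TRUE)
    } else {
      v <- sample(100, n1 + n2)
      x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    }
    got <- rank_sum_test(x, y)
    expect_equal(got$p_two_sided, oracle_rank_sum_p(x, y), tolerance = 1e-12)
    expect_true(got$u_statistic >= 0 && got$u_statistic <= n1 * n2)
  }
})

test_that("large tied samples fall back to the corrected normal approximation", {
  set.seed(4)
  x <- sample(1:6, 40, replace = TRUE)
  y <- sample(1:6, 45, replace = TRUE)
  got <- rank_sum_test(x, y)
  expect_equal(got$method, "normal-approximation-with-tie-correction")
  expect_equal(got$p_two_sided,
               suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                   correct = TRUE))$p.value)
})

test_that("AEI statistics are invariant to sample order", {
  set.seed(8)
  co <- simulate_cohort(56, fixture_haplotype_model(), seed = 12)
  ex <- simulate_expression(co, sim_config(aei_effect = 1.3), seed = 13)
  het <- which(!is.na(ex$allelic_ratio_obs))
  rec <- data.frame(sample_id = co$sample_id[het],
                    aei_magnitude = aei_magnitude(ex$allelic_ratio_obs[het]),
                    included = TRUE)
  t1 <- conditional_aei_test(rec, co, "rs35349669", "rs10933431")
  perm <- sample(nrow(rec))
  t2 <- conditional_aei_test(rec[perm, ], co[sample(nrow(co)), ],
                             "rs35349669", "rs10933431")
  expect_equal(t1$test$p_two_sided, t2$test$p_two_sided)
  expect_equal(sort(t1$magnitudes$heterozygous),
               sort(t2$magnitudes$heterozygous))
})

test_that("conditional test power rises with the simulated allelic effect", {
  reps <- 120
  rate_at <- function(effect) {
    rej <- vapply(seq_len(reps), function(s) {
      co <- simulate_cohort(56, fixture_haplotype_model(),
                            seed = derive_seed(s, paste0("pw", effect)))
      ex <- simulate_expression(co, sim_config(aei_effect = effect),
                                seed = derive_seed(s, "pwex"))
      het <- which(!is.na(ex$allelic_ratio_obs))
      if (length(het) < 4) return(NA)
      rec <- data.frame(sample_id = co$sample_id[het],
                        aei_magnitude = aei_magnitude(ex$allelic_ratio_obs[het]),
                        included = TRUE)
      t <- tryCatch(conditional_aei_test(rec, co, "rs35349669", "rs10933431"),
                    error = function(e) NULL)
      if (is.null(t)) NA else t$test$p_two_sided < 0.05
    }, logical(1))
    mean(rej, na.rm = TRUE)
  }
  r <- vapply(c(1.05, 1.12, 1.30), rate_at, numeric(1))
  expect_gt(r[3], r[1])
  expect_true(r[2] >= r[1] - 0.05 && r[3] >= r[2] - 0.05)
})

test_that("aei_records joins materials, filters depth and normalizes", {
  mk <- function(id, mat, a, b) data.frame(
    sample_id = id, material = mat, n_allele1 = a, n_allele2 = b,
    n_ambiguous = 0L, n_unassigned = 0L, n_total = a + b)
  counts <- rbind(mk("s1", "cDNA", 1200L, 1000L), mk("s1", "gDNA", 990L, 1000L),
                  mk("s2", "cDNA", 900L, 1000L), mk("s2", "gDNA", 1010L, 1000L),
                  mk("s3", "cDNA", 30L, 40L),   mk("s3", "gDNA", 35L, 30L))
  rec <- aei_records(counts, min_depth = 100)
  expect_false(rec$included[rec$sample_id == "s3"])  # shallow sample dropped
  inc <- rec[rec$included, ]
  gmean <- mean(c(990 / 1000, 1010 / 1000))
  expect_equal(inc$normalized_ratio,
               c(1.2, 0.9) / gmean, tolerance = 1e-12)
  expect_lt(abs(mean(inc$normalized_ratio - mean(inc$normalized_ratio))), 1e-12)
  recp <- aei_records(counts, min_depth = 100, mode = "paired")
  expect_equal(recp$normalized_ratio[recp$sample_id == "s1"],
               1.2 / 0.99, tolerance = 1e-12)
})
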