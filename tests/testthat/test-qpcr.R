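# Standard-curve quantitation, relative expression, expression models and
# the CHX trend test.

test_that("standard curves recover slope, efficiency and copies", {
  std <- data.frame(copies = 10^(1:6), cq = 40 - 3.3219 * (1:6))
  cv <- fit_standard_curve(std)
  expect_equal(cv$slope, -3.3219, tolerance = 1e-9)
  expect_equal(cv$efficiency, 10^(1 / 3.3219) - 1, tolerance = 1e-9)
  expect_equal(cv$efficiency, 1.0, tolerance = 1e-4)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  # exact two-point interpolation
  cv2 <- fit_standard_curve(data.frame(copies = c(10, 100), cq = c(36.7, 33.4)))
  expect_equal(cv2$slope, -3.3, tolerance = 1e-9)
  expect_error(fit_standard_curve(data.frame(copies = c(10, 10), cq = c(1, 2))),
               "two distinct")
  expect_warning(
    rej <- fit_standard_curve(data.frame(copies = c(10, 100), cq = c(30, 33))),
    "rejected")
  expect_true(rej$rejected)
})

test_that("Cq converts to copies by the curve's closed form", {
  cv <- list(slope = -3.0, intercept = 40)
  expect_equal(cq_to_copies(40, cv)$copies, 1)
  expect_equal(cq_to_copies(31, cv)$copies, 1000)
  below <- cq_to_copies(43, cv)
  expect_equal(below$copies, 0.1, tolerance = 1e-12)
  expect_true(below$below_range)
})

test_that("simulated standards round-trip to true copies within 1e-9", {
  es <- data.frame(sample_id = "S1", itgam = 3177.2, ex10_ex12 = 12345.6)
  curve0 <- list(slope = -3.3219, intercept = 37)
  plate <- simulate_qpcr_plate(es, curve0, qpcr_sd = 0, seed = 1,
                               assays = c("itgam", "ex10_ex12"))
  q <- quantitate_plate(plate)
  for (a in c("itgam", "ex10_ex12")) {
    got <- q$copies$copies[q$copies$assay == a]
    expect_equal(got / es[[a]], 1, tolerance = 1e-9)
  }
})

test_that("relative expression computes ratios on the expected scale", {
  r <- relative_expression(1047, 10)
  expect_equal(r$ratio, 104.7)
  expect_equal(r$log_ratio, log10(104.7), tolerance = 1e-12)
  same <- relative_expression(250, 250)
  expect_equal(c(same$ratio, same$log_ratio), c(1, 0))
  expect_error(relative_expression(10, 0), "positive")
})

test_that("expression model returns standardized betas matching closed form", {
  set.seed(10)
  df <- data.frame(x1 = rnorm(8), x2 = rnorm(8))
  df$y <- 1.5 + 2 * df$x1 - 0.7 * df$x2 + rnorm(8, 0, 0.5)
  fit <- fit_expression_model(df, "y", c("x1", "x2"))
  # normal-equations oracle on z-scored data
  z <- scale(as.matrix(df[c("y", "x1", "x2")]))
  X <- cbind(1, z[, c("x1", "x2")])
  beta <- solve(t(X) %*% X, t(X) %*% z[, "y"])
  expect_equal(unname(fit$beta_std), unname(beta[2:3, 1]), tolerance = 1e-10)
  expect_true(fit$adj_r_squared <= fit$r_squared)
  # identity fit
  df2 <- data.frame(x = rnorm(10)); df2$y <- df2$x
  fit2 <- suppressWarnings(fit_expression_model(df2, "y", "x"))
  expect_equal(unname(fit2$beta_std), 1, tolerance = 1e-9)
  expect_equal(fit2$adj_r_squared, 1, tolerance = 1e-9)
  # null property at large n
  set.seed(11)
  df3 <- data.frame(x = rnorm(4000)); df3$y <- rnorm(4000)
  fit3 <- fit_expression_model(df3, "y", "x")
  expect_lt(abs(fit3$beta_std[["x"]]), 0.06)
  expect_lt(fit3$adj_r_squared, 0.01)
  # guards
  df4 <- data.frame(x = rnorm(10), k = 1); df4$y <- df4$x
  expect_error(fit_expression_model(df4, "y", c("x", "k")), "constant")
})

test_that("a sole predictor's standardized beta equals Pearson r", {
  set.seed(12)
  for (i in 1:10) {
    df <- data.frame(x = rnorm(30))
    df$y <- 0.4 * df$x + rnorm(30)
    fit <- fit_expression_model(df, "y", "x")
    expect_equal(unname(fit$beta_std), cor(df$x, df$y), tolerance = 1e-12)
  }
})

test_that("betas and R2 are invariant under affine predictor rescaling", {
  set.seed(13)
  df <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  df$y <- df$x1 - df$x2 + rnorm(40)
  f1 <- fit_expression_model(df, "y", c("x1", "x2"))
  df$x1 <- 100 * df$x1 - 7; df$x2 <- 0.01 * df$x2 + 3
  f2 <- fit_expression_model(df, "y", c("x1", "x2"))
  expect_equal(f1$beta_std, f2$beta_std, tolerance = 1e-10)
  expect_equal(f1$adj_r_squared, f2$adj_r_squared, tolerance = 1e-12)
})

test_that("regression recovers the simulated NIARI fold effect", {
  fold <- 1.5
  coefs <- vapply(1:500, function(s) {
    co <- simulate_cohort(56, fixture_haplotype_model(),
                          seed = derive_seed(s, "niari_cohort"))
    ex <- simulate_expression(co, sim_config(niari_fold = c(
      itgam = 1, ex10_ex12 = fold, ex2_ex3 = 1, ex11_ex12 = 1,
      in14_ex16 = 1, ex15_ex16 = 1, ex26_present = 1, d47 = 1)),
      seed = derive_seed(s, "niari_expr"))
    df <- data.frame(y = log10(ex$ex10_ex12), x = log10(ex$itgam),
                     niari = as.numeric(co$niari == "high"))
    fit_expression_model(df, "y", c("x", "niari"))$coef_raw[["niari"]]
  }, numeric(1))
  expect_gte(mean(coefs > 0), 0.95)                    # sign recovery
  expect_lt(abs(mean(coefs) - log10(fold)), 0.1 * log10(fold))
})

test_that("genotype dose codings count minor alleles", {
  g <- c("TT", "TC", "CC", "CT")
  expect_equal(genotype_dose(g, "rs35349669"), c(2, 1, 0, 1))
  expect_equal(genotype_dose(g, "rs35349669", "dominant"), c(1, 1, 0, 1))
  expect_equal(genotype_dose(g, "rs35349669", "recessive"), c(1, 0, 0, 0))
})

test_that("CHX trend detects the programmed accumulation slope", {
  p <- list(baseline = 0.13, increment = 0.02, timepoints = c(1, 3, 5, 8),
            replicates = 3, noise_sd = 0)
  tr <- suppressWarnings(chx_trend(simulate_chx_timecourse(p, seed = 1)))
  expect_equal(tr$slope, 0.02, tolerance = 1e-12)
  expect_equal(tr$arm_contrast, 0.02, tolerance = 1e-12)
  # constructed monotone input gives a positive slope and contrast
  tc <- data.frame(time_h = rep(c(1, 3, 5, 8), 2),
                   treatment = rep(c("CHX", "vehicle"), each = 4),
                   replicate = 1,
                   d47_fraction = c(0.15, 0.19, 0.23, 0.29,
                                    0.14, 0.13, 0.15, 0.14))
  tr2 <- suppressWarnings(chx_trend(tc))
  expect_gt(tr2$slope, 0)
  expect_gt(tr2$arm_contrast, 0)
  # flat input
  tcf <- tc; tcf$d47_fraction <- 0.2
  expect_equal(suppressWarnings(chx_trend(tcf))$slope, 0)
  expect_error(chx_trend(tc[tc$time_h == 1, ]), ">= 2 CHX timepoints")
  # noisy simulated course still shows a significant positive slope
  pn <- p; pn$noise_sd <- 0.01
  trn <- chx_trend(simulate_chx_timecourse(pn, seed = 5))
  expect_gt(trn$slope, 0)
  expect_lt(trn$p_slope, 0.01)
})
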