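# Standard-curve quantitation, relative expression, expression linear models
# with standardized coefficients, and the CHX time-course trend test.

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of Cq on log10(copies) over a dilution series.
#' The amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (1.0 = perfect doubling, slope -3.32).
#'
#' @param standards data.frame with `copies` (> 0) and `cq`; at least two
#'   distinct copy levels.
#' @return Object of class `standard_curve`: `slope`, `intercept` (Cq at one
#'   copy), `efficiency`, `r_squared`, `rejected` (TRUE when the slope is
#'   non-negative, with a warning).
#' @export
fit_standard_curve <- function(standards) {
  abort_if(any(standards$copies <= 0), "standard copies must be positive")
  abort_if(length(unique(standards$copies)) < 2,
           "need at least two distinct copy levels")
  fit <- stats::lm(cq ~ log10(copies), data = standards)
  slope <- unname(stats::coef(fit)[2])
  rejected <- FALSE
  if (slope >= 0) {
    warning("standard curve has non-negative slope; curve flagged as rejected")
    rejected <- TRUE
  }
  # computed directly so that noise-free dilution series (SST explained
  # exactly) do not trip summary.lm's perfect-fit warning
  sst <- sum((standards$cq - mean(standards$cq))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2,
                 rejected = rejected),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.4f, intercept %.2f, efficiency %.3f, R^2 %.4f%s\n",
              x$slope, x$intercept, x$efficiency, x$r_squared,
              if (x$rejected) " [REJECTED]" else ""))
  invisible(x)
}

#' Convert Cq values to copy numbers via a standard curve
#'
#' `copies = 10^((cq - intercept) / slope)`. Sub-single-copy results are
#' returned (not censored) and flagged below range.
#'
#' @param cq Numeric vector of quantification cycles.
#' @param curve A `standard_curve`.
#' @return data.frame: `cq`, `copies`, `below_range`.
#' @export
cq_to_copies <- function(cq, curve) {
  copies <- 10^((cq - curve$intercept) / curve$slope)
  data.frame(cq = cq, copies = copies, below_range = copies < 1)
}

#' Relative expression of a target against a reference assay
#'
#' @param target_copies,reference_copies Positive copy numbers (vectorised).
#' @param sample_id,assay,reference_assay Optional labels.
#' @return data.frame: labels, `target_copies`, `reference_copies`, `ratio`,
#'   `log_ratio` (log10).
#' @export
relative_expression <- function(target_copies, reference_copies,
                                sample_id = NA_character_,
                                assay = NA_character_,
                                reference_assay = NA_character_) {
  abort_if(any(target_copies <= 0) || any(reference_copies <= 0),
           "copy numbers must be positive")
  ratio <- target_copies / reference_copies
  data.frame(sample_id = sample_id, assay = assay,
             reference_assay = reference_assay,
             target_copies = target_copies,
             reference_copies = reference_copies,
             ratio = ratio, log_ratio = log10(ratio),
             stringsAsFactors = FALSE)
}

#' Average replicate Cq values per sample and assay
#'
#' Unknown wells only; replicates are averaged before quantitation.
#'
#' @param plate Plate table as from [simulate_qpcr_plate()].
#' @return data.frame: `sample`, `assay`, `cq` (mean), `n_replicates`.
#' @export
average_replicates <- function(plate) {
  unk <- plate[plate$well_type == "unknown", , drop = FALSE]
  agg <- stats::aggregate(cq ~ sample + assay, data = unk, FUN = mean)
  n <- stats::aggregate(cq ~ sample + assay, data = unk, FUN = length)
  agg$n_replicates <- n$cq
  agg
}

#' Quantitate a plate against its own standard wells
#'
#' Refits the standard curve per assay from the plate's dilution wells,
#' averages replicate Cq values, and converts to copies.
#'
#' @param plate Plate table with `standard` and `unknown` wells.
#' @return List: `curves` (per assay), `copies` (data.frame `sample`,
#'   `assay`, `cq`, `copies`, `below_range`).
#' @export
quantitate_plate <- function(plate) {
  assays <- unique(plate$assay)
  curves <- lapply(stats::setNames(assays, assays), function(a) {
    std <- plate[plate$assay == a & plate$well_type == "standard", ]
    abort_if(nrow(std) == 0, "no standard wells for assay %s", a)
    fit_standard_curve(data.frame(copies = std$copies, cq = std$cq))
  })
  means <- average_replicates(plate)
  out <- do.call(rbind, lapply(assays, function(a) {
    m <- means[means$assay == a, ]
    cbind(m[c("sample", "assay")], cq_to_copies(m$cq, curves[[a]])[-1])
  }))
  rownames(out) <- NULL
  list(curves = curves, copies = out)
}

#' Fit an expression linear model with standardized coefficients
#'
#' Ordinary least squares of a (log-transformed) response on z-scored
#' predictors, with the response z-scored too, so each coefficient is a
#' standardized beta (for a single predictor it equals the Pearson
#' correlation). Raw-scale coefficients, nominal two-sided p values and the
#' adjusted R-squared are also returned. Genotypes should be coded as
#' additive minor-allele dose (see [genotype_dose()]); dominant or recessive
#' codings can be passed instead.
#'
#' @param data data.frame holding the response and predictor columns.
#' @param response Response column name (typically log10 copies).
#' @param predictors Character vector of predictor column names (e.g. log10
#'   reference copies, a 0/1 NIARI indicator, a genotype dose).
#' @return Object of class `expression_model_fit`: `beta_std`, `coef_raw`,
#'   `p_values`, `r_squared`, `adj_r_squared`, `n`, `fit` (the raw-scale lm).
#' @export
fit_expression_model <- function(data, response, predictors) {
  abort_if(!response %in% names(data), "missing response column %s", response)
  miss <- setdiff(predictors, names(data))
  abort_if(length(miss) > 0, "missing predictor column(s): %s",
           paste(miss, collapse = ", "))
  df <- data[c(response, predictors)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  abort_if(nrow(df) < length(predictors) + 2,
           "need at least %d complete rows, got %d",
           length(predictors) + 2, nrow(df))
  const <- predictors[vapply(df[predictors], function(x) stats::sd(x) == 0,
                             logical(1))]
  abort_if(length(const) > 0, "constant predictor column(s): %s",
           paste(const, collapse = ", "))

  fml <- stats::reformulate(predictors, response)
  fit_raw <- stats::lm(fml, data = df)
  abort_if(fit_raw$rank < length(predictors) + 1,
           "rank-deficient design; collinear column(s): %s",
           paste(names(which(is.na(stats::coef(fit_raw)))), collapse = ", "))

  zdf <- as.data.frame(lapply(df, function(x) as.numeric(scale(x))))
  fit_z <- stats::lm(fml, data = zdf)
  sm <- summary(fit_raw)

  structure(list(
    response = response,
    predictors = predictors,
    beta_std = stats::coef(fit_z)[predictors],
    coef_raw = stats::coef(fit_raw)[predictors],
    p_values = sm$coefficients[predictors, "Pr(>|t|)"],
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = nrow(df),
    fit = fit_raw
  ), class = "expression_model_fit")
}

#' @export
print.expression_model_fit <- function(x, ...) {
  cat(sprintf("Expression model: %s ~ %s (n = %d, adj R^2 = %.3f)\n",
              x$response, paste(x$predictors, collapse = " + "), x$n,
              x$adj_r_squared))
  for (p in x$predictors)
    cat(sprintf("  %-16s std beta = %+.3f, p = %.3g\n", p, x$beta_std[[p]],
                x$p_values[[p]]))
  invisible(x)
}

#' Additive genotype coding (minor-allele dose)
#'
#' @param genotypes Character vector of genotype strings (allele order free).
#' @param snp SNP name with a registered allele pair
#'   (rs35349669 / rs10933431 / rs1141328).
#' @param coding `"additive"` (0/1/2 minor alleles, default), `"dominant"`
#'   (any minor = 1) or `"recessive"` (two minors = 1).
#' @return Numeric vector.
#' @export
genotype_dose <- function(genotypes, snp, coding = c("additive", "dominant",
                                                     "recessive")) {
  coding <- match.arg(coding)
  minor <- snp_alleles[[snp]][["minor"]]
  dose <- vapply(strsplit(genotypes, ""), function(a) sum(a == minor),
                 numeric(1))
  switch(coding,
         additive = dose,
         dominant = as.numeric(dose > 0),
         recessive = as.numeric(dose == 2))
}

#' Trend of an NMD-target splice fraction over a CHX time course
#'
#' Least-squares slope of the fraction on treatment hours within the CHX arm,
#' plus the arm contrast (difference between the CHX and vehicle slopes, with
#' the interaction p value from a two-arm model). A Spearman rank-correlation
#' p for the CHX arm is included as a distribution-free check.
#'
#' @param timecourse data.frame as from [simulate_chx_timecourse()]
#'   (`time_h`, `treatment`, `d47_fraction`).
#' @return Object of class `chx_trend_result`: `slope`, `p_slope`,
#'   `slope_vehicle`, `arm_contrast`, `p_contrast`, `spearman_p`.
#' @export
chx_trend <- function(timecourse) {
  chx <- timecourse[timecourse$treatment == "CHX", ]
  veh <- timecourse[timecourse$treatment == "vehicle", ]
  abort_if(length(unique(chx$time_h)) < 2,
           "need >= 2 CHX timepoints for a trend")
  fit <- stats::lm(d47_fraction ~ time_h, data = chx)
  sm <- summary(fit)$coefficients
  slope <- unname(stats::coef(fit)["time_h"])
  p_slope <- if (nrow(chx) > 2) sm["time_h", "Pr(>|t|)"] else NA_real_

  slope_v <- NA_real_; contrast <- NA_real_; p_contrast <- NA_real_
  if (nrow(veh) > 0 && length(unique(veh$time_h)) >= 2) {
    slope_v <- unname(stats::coef(stats::lm(d47_fraction ~ time_h,
                                            data = veh))["time_h"])
    contrast <- slope - slope_v
    both <- rbind(chx, veh)
    both$is_chx <- as.numeric(both$treatment == "CHX")
    fit2 <- stats::lm(d47_fraction ~ time_h * is_chx, data = both)
    cf <- summary(fit2)$coefficients
    if ("time_h:is_chx" %in% rownames(cf))
      p_contrast <- cf["time_h:is_chx", "Pr(>|t|)"]
  }
  sp <- if (nrow(chx) >= 3 && stats::sd(chx$d47_fraction) > 0) {
    suppressWarnings(stats::cor.test(chx$time_h, chx$d47_fraction,
                                     method = "spearman"))$p.value
  } else NA_real_

  structure(list(slope = slope, p_slope = p_slope,
                 slope_vehicle = slope_v, arm_contrast = contrast,
                 p_contrast = p_contrast, spearman_p = sp),
            class = "chx_trend_result")
}

#' @export
print.chx_trend_result <- function(x, ...) {
  cat(sprintf("CHX trend: slope %.4f /h (p = %.3g), arm contrast %.4f (p = %.3g)\n",
              x$slope, x$p_slope, x$arm_contrast, x$p_contrast))
  invisible(x)
}
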