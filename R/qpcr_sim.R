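# qPCR plate and cycloheximide time-course simulators.

#' Simulate a qPCR plate from expression states and a standard curve
#'
#' For every sample x assay x replicate, `Cq = intercept + slope *
#' log10(copies) + Normal(0, qpcr_sd)`. A ten-fold standard-dilution series
#' (10^1..10^6 copies, duplicate wells) is emitted per assay so the curve can
#' be refit from the plate alone.
#'
#' @param expression_states data.frame from [simulate_expression()].
#' @param curve A `standard_curve` (see [fit_standard_curve()]) or a list with
#'   `slope` (< 0) and `intercept`.
#' @param qpcr_sd Cq noise SD (0 gives noise-free wells).
#' @param seed Integer seed.
#' @param replicates Replicate wells per sample x assay (default 3).
#' @param assays Assays to plate (default all of [assay_names()]).
#' @return data.frame: `sample`, `assay`, `replicate`, `well_type`
#'   (`unknown`/`standard`), `copies` (known input for standards, NA
#'   otherwise), `cq`.
#' @export
simulate_qpcr_plate <- function(expression_states, curve, qpcr_sd = 0.15,
                                seed = 1L, replicates = 3L,
                                assays = setdiff(assay_names(), character(0))) {
  abort_if(curve$slope >= 0, "standard-curve slope must be negative")
  assays <- intersect(assays, names(expression_states))
  abort_if(length(assays) == 0, "no requested assay found in expression_states")
  cp <- unlist(expression_states[assays], use.names = FALSE)
  abort_if(any(cp <= 0), "copies must be positive")

  unk <- expand.grid(replicate = seq_len(replicates),
                     sample = expression_states$sample_id,
                     assay = assays,
                     stringsAsFactors = FALSE)
  unk$well_type <- "unknown"
  unk$copies_true <- mapply(function(s, a)
    expression_states[[a]][expression_states$sample_id == s],
    unk$sample, unk$assay)

  std <- expand.grid(replicate = 1:2,
                     copies_true = 10^(1:6),
                     assay = assays,
                     stringsAsFactors = FALSE)
  std$sample <- sprintf("STD_%d", round(log10(std$copies_true)))
  std$well_type <- "standard"

  plate <- rbind(unk[c("sample", "assay", "replicate", "well_type", "copies_true")],
                 std[c("sample", "assay", "replicate", "well_type", "copies_true")])
  with_seed(seed, {
    plate$cq <- curve$intercept + curve$slope * log10(plate$copies_true) +
      stats::rnorm(nrow(plate), 0, qpcr_sd)
  })
  plate$copies <- ifelse(plate$well_type == "standard", plate$copies_true, NA_real_)
  plate$copies_true <- NULL
  rownames(plate) <- NULL
  plate
}

#' Simulate a cycloheximide (CHX) time course of a decay-sensitive isoform
#'
#' Models accumulation of an NMD-target splice fraction under translation
#' inhibition: the CHX arm's fraction rises linearly with treatment time
#' (`baseline + increment * hours + noise`, truncated to `[0, 1]`) while the
#' vehicle arm stays flat at baseline.
#'
#' @param chx_params List: `baseline` (starting fraction in `[0, 1]`),
#'   `increment` (fraction per hour), `timepoints` (hours, nonempty),
#'   `replicates` (>= 1), `noise_sd`.
#' @param seed Integer seed.
#' @return data.frame: `time_h`, `treatment` (`CHX`/`vehicle`), `replicate`,
#'   `d47_fraction`.
#' @export
simulate_chx_timecourse <- function(chx_params = sim_config()$chx_params,
                                    seed = 1L) {
  p <- chx_params
  abort_if(p$baseline < 0 || p$baseline > 1, "baseline must lie in [0, 1]")
  abort_if(length(p$timepoints) == 0, "timepoints must be nonempty")
  abort_if(p$replicates < 1, "replicates must be >= 1")
  noise_sd <- p$noise_sd %||% 0

  grid <- expand.grid(replicate = seq_len(p$replicates),
                      treatment = c("CHX", "vehicle"),
                      time_h = p$timepoints,
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    mu <- ifelse(grid$treatment == "CHX",
                 p$baseline + p$increment * grid$time_h,
                 p$baseline)
    grid$d47_fraction <- pmin(1, pmax(0, mu + stats::rnorm(nrow(grid), 0, noise_sd)))
  })
  grid[c("time_h", "treatment", "replicate", "d47_fraction")]
}
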