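# Allelic-expression-imbalance statistics: gDNA normalization, the
# absolute-deviation AEI magnitude, conditional genotype stratification and
# the rank-sum test.

#' Normalize cDNA allelic ratios to genomic-DNA control ratios
#'
#' Genomic DNA carries the two alleles 1:1, so its measured ratio captures
#' amplification and counting bias; dividing the cDNA ratio by it cancels
#' that bias. `cohort_mean` mode (default) divides every cDNA ratio by the
#' mean of all gDNA ratios — matching a study design that reports a single
#' gDNA control mean — while `paired` mode divides each sample's cDNA ratio
#' by its own gDNA ratio.
#'
#' @param cdna_ratios Named or plain numeric vector of cDNA G:A ratios (> 0).
#' @param gdna_ratios Numeric vector of gDNA ratios (> 0); in `paired` mode it
#'   must align 1:1 with `cdna_ratios`.
#' @param mode `"cohort_mean"` or `"paired"`.
#' @return Numeric vector of normalized ratios, same length/names as
#'   `cdna_ratios`.
#' @export
normalize_to_gdna <- function(cdna_ratios, gdna_ratios,
                              mode = c("cohort_mean", "paired")) {
  mode <- match.arg(mode)
  abort_if(length(gdna_ratios) == 0, "gDNA ratio set is empty")
  abort_if(any(cdna_ratios <= 0) || any(gdna_ratios <= 0),
           "ratios must be positive")
  if (mode == "cohort_mean") {
    cdna_ratios / mean(gdna_ratios)
  } else {
    abort_if(length(gdna_ratios) != length(cdna_ratios),
             "paired mode needs one gDNA ratio per cDNA sample (%d vs %d)",
             length(gdna_ratios), length(cdna_ratios))
    cdna_ratios / gdna_ratios
  }
}

#' Per-sample AEI magnitude: absolute deviation from the cohort mean
#'
#' The imbalance statistic is `|r_i - mean(r)|` over the analyzed
#' heterozygous-reporter samples, i.e. how far each sample's normalized
#' allelic ratio sits from the cohort's average ratio, regardless of
#' direction. With `anchor = 1` the deviation is taken from perfect balance
#' instead of the empirical mean.
#'
#' @param normalized_ratios Numeric vector (>= 2 samples).
#' @param anchor `"mean"` (default) or a numeric anchor such as 1.
#' @return Numeric vector of magnitudes.
#' @export
aei_magnitude <- function(normalized_ratios, anchor = "mean") {
  abort_if(length(normalized_ratios) < 2,
           "AEI magnitude needs at least 2 samples")
  ctr <- if (identical(anchor, "mean")) mean(normalized_ratios) else anchor
  abs(normalized_ratios - ctr)
}

#' Stratify samples for a conditional (phase-safe) AEI test
#'
#' Two partially linked SNPs with unknown phase can confound each other's
#' allelic effects in double heterozygotes. The conditional design retains
#' only samples homozygous at the conditioning SNP — fixing that SNP's
#' contribution on both chromosomes — and then splits by zygosity at the test
#' SNP, pooling both homozygote classes against heterozygotes.
#'
#' @param genotype_table data.frame with one row per sample and
#'   `genotype_<snp>` columns (a `sample_id` column is carried through when
#'   present).
#' @param test_snp,conditioning_snp SNP names, e.g. `"rs35349669"`.
#' @return Object of class `stratified_groups`: lists of row indices / sample
#'   ids for `group_homozygous` and `group_heterozygous`, plus `n_excluded`.
#' @export
stratify_for_conditional_test <- function(genotype_table, test_snp,
                                          conditioning_snp) {
  tcol <- paste0("genotype_", test_snp)
  ccol <- paste0("genotype_", conditioning_snp)
  abort_if(!tcol %in% names(genotype_table), "missing column %s", tcol)
  abort_if(!ccol %in% names(genotype_table), "missing column %s", ccol)
  ids <- genotype_table$sample_id %||% sprintf("row%d", seq_len(nrow(genotype_table)))
  if (nrow(genotype_table) == 0) {
    return(structure(list(test_snp = test_snp,
                          conditioning_snp = conditioning_snp,
                          group_homozygous = character(0),
                          group_heterozygous = character(0),
                          n_excluded = 0L),
                     class = "stratified_groups"))
  }
  check_geno <- function(col, snp) {
    g <- genotype_table[[col]]
    al <- sort(unname(snp_alleles[[snp]]))
    ok <- !is.na(g) & nchar(g) == 2 &
      vapply(strsplit(g, ""), function(x) all(x %in% al), logical(1))
    abort_if(any(!ok), "unknown genotype codes for %s in rows: %s",
             snp, paste(which(!ok), collapse = ", "))
  }
  check_geno(tcol, test_snp)
  check_geno(ccol, conditioning_snp)

  keep <- !is_het(genotype_table[[ccol]])
  het_test <- is_het(genotype_table[[tcol]])
  structure(list(
    test_snp = test_snp,
    conditioning_snp = conditioning_snp,
    group_homozygous = ids[keep & !het_test],
    group_heterozygous = ids[keep & het_test],
    n_excluded = sum(!keep)
  ), class = "stratified_groups")
}

#' @export
print.stratified_groups <- function(x, ...) {
  cat(sprintf(
    "Conditional strata for %s (conditioning on %s homozygotes):\n  homozygous n = %d, heterozygous n = %d, excluded n = %d\n",
    x$test_snp, x$conditioning_snp, length(x$group_homozygous),
    length(x$group_heterozygous), x$n_excluded))
  invisible(x)
}

# exact two-sided rank-sum p by full enumeration of group labelings;
# handles ties (midranks enter U in halves)
.rank_sum_enumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  labelings <- utils::combn(n1 + n2, n1)
  us <- apply(labelings, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Computes the U statistic for group 1 and a two-sided p value. Small
#' samples get an exact null: the tie-free exact distribution when there are
#' no ties, or full enumeration of group labelings when ties are present and
#' the labeling space is enumerable; otherwise the normal approximation with
#' tie and continuity correction (via [stats::wilcox.test()]) is used.
#'
#' @param values_group1,values_group2 Nonempty numeric vectors.
#' @return Object of class `rank_sum_result`: `u_statistic`, `n1`, `n2`,
#'   `p_two_sided`, `method`.
#' @export
rank_sum_test <- function(values_group1, values_group2) {
  abort_if(length(values_group1) == 0 || length(values_group2) == 0,
           "both groups must be nonempty")
  x <- values_group1; y <- values_group2
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  small <- min(n1, n2) <= 10 && (n1 + n2) <= 30

  if (small && !has_ties) {
    # exact symmetric null of U via pwilcox
    lo <- min(u, n1 * n2 - u)
    p <- min(1, 2 * stats::pwilcox(lo, n1, n2))
    method <- "exact"
  } else if (has_ties && choose(n1 + n2, n1) <= 2e5) {
    p <- .rank_sum_enumerate(x, y)
    method <- "exact"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    p <- wt$p.value
    method <- "normal-approximation-with-tie-correction"
  }
  structure(list(u_statistic = u, n1 = n1, n2 = n2,
                 p_two_sided = p, method = method),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Build the per-sample AEI record table
#'
#' Joins cDNA and gDNA allelic ratios per sample, applies depth filtering and
#' gDNA normalization, and attaches the AEI magnitude (absolute deviation of
#' the normalized ratio from the cohort mean over included samples).
#'
#' @param counts_table data.frame of stacked [count_alleles()] rows (columns
#'   `sample_id`, `material`, counts).
#' @param min_depth Minimum assigned depth per sample x material.
#' @param mode Normalization mode, see [normalize_to_gdna()].
#' @param anchor Deviation anchor, see [aei_magnitude()].
#' @return data.frame of class `aei_records`: one row per sample with
#'   `raw_ratio_cdna`, `raw_ratio_gdna`, `normalized_ratio`, `aei_magnitude`,
#'   `included`.
#' @export
aei_records <- function(counts_table, min_depth = 100L,
                        mode = c("cohort_mean", "paired"), anchor = "mean") {
  mode <- match.arg(mode)
  get_ratio <- function(mat) {
    sub <- counts_table[counts_table$material == mat, , drop = FALSE]
    stats::setNames(
      vapply(seq_len(nrow(sub)), function(i) {
        row <- sub[i, , drop = FALSE]
        if (row$n_allele2 == 0) return(NA_real_)
        rr <- allelic_ratio(row, min_depth)
        if (rr$pass_depth) rr$ratio else NA_real_
      }, numeric(1)),
      sub$sample_id)
  }
  rc <- get_ratio("cDNA")
  rg <- get_ratio("gDNA")
  ids <- names(rc)
  gd <- rg[ids]
  ok <- !is.na(rc) & (if (mode == "paired") !is.na(gd) else TRUE)
  abort_if(sum(!is.na(rg)) == 0, "no usable gDNA ratios for normalization")

  norm <- rep(NA_real_, length(ids))
  if (mode == "cohort_mean") {
    norm[ok] <- normalize_to_gdna(rc[ok], rg[!is.na(rg)], mode = "cohort_mean")
  } else {
    norm[ok] <- normalize_to_gdna(rc[ok], gd[ok], mode = "paired")
  }
  mag <- rep(NA_real_, length(ids))
  mag[ok] <- aei_magnitude(norm[ok], anchor = anchor)

  out <- data.frame(sample_id = ids,
                    raw_ratio_cdna = unname(rc),
                    raw_ratio_gdna = unname(gd),
                    normalized_ratio = norm,
                    aei_magnitude = mag,
                    included = unname(ok),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("aei_records", class(out))
  out
}

#' Conditional genotype-stratified AEI test
#'
#' Runs the phase-safe conditional design end to end: restricts to samples
#' homozygous at the conditioning SNP, splits by test-SNP zygosity, and
#' compares AEI magnitudes between the two strata with the two-sided
#' rank-sum test.
#'
#' @param records [aei_records()] table (only `included` rows are used).
#' @param sample_sheet Cohort table with genotype columns.
#' @param test_snp,conditioning_snp SNP names.
#' @return List: `strata` (`stratified_groups`), `test` (`rank_sum_result`),
#'   `magnitudes` (named list of the two groups' magnitude vectors).
#' @export
conditional_aei_test <- function(records, sample_sheet, test_snp,
                                 conditioning_snp) {
  strata <- stratify_for_conditional_test(sample_sheet, test_snp,
                                          conditioning_snp)
  m <- stats::setNames(records$aei_magnitude, records$sample_id)
  g_hom <- m[intersect(strata$group_homozygous,
                       records$sample_id[records$included])]
  g_het <- m[intersect(strata$group_heterozygous,
                       records$sample_id[records$included])]
  list(strata = strata,
       test = rank_sum_test(unname(g_hom), unname(g_het)),
       magnitudes = list(homozygous = g_hom, heterozygous = g_het))
}
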