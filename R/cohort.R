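# Cohort simulation and the packaged reference-cohort fixture.
#
# SNP conventions used throughout:
#   rs35349669  minor = T, major = C   (intron-10 risk SNP, MAF ~ 0.50)
#   rs10933431  minor = G, major = C   (intron-2 protective SNP, MAF ~ 0.22)
#   rs1141328   alleles G / A          (5'UTR reporter SNP, high MAF)
# Heterozygotes are written minor-first ("TC", "GC", "GA"); readers accept
# either allele order.

snp_alleles <- list(
  rs35349669 = c(minor = "T", major = "C"),
  rs10933431 = c(minor = "G", major = "C"),
  rs1141328  = c(minor = "G", major = "A")
)

# canonical genotype string from two allele characters
canon_genotype <- function(a1, a2, snp) {
  al <- snp_alleles[[snp]]
  n_minor <- (a1 == al["minor"]) + (a2 == al["minor"])
  c(paste0(al["major"], al["major"]),
    paste0(al["minor"], al["major"]),
    paste0(al["minor"], al["minor"]))[n_minor + 1L]
}

#' Is a genotype string heterozygous?
#' @param genotype Character vector of two-letter genotype strings.
#' @return Logical vector.
#' @export
is_het <- function(genotype) {
  substr(genotype, 1, 1) != substr(genotype, 2, 2)
}

#' Simulate a brain-bank style cohort with two linked AD SNPs and an unlinked
#' reporter SNP
#'
#' Genotypes at the two AD-associated SNPs are drawn as two independent
#' haplotypes from a [haplotype_frequencies()] model; the reporter SNP is drawn
#' independently per chromosome (it is not co-inherited with either AD SNP).
#' The AD / non-AD split is exact — `round(n * ad_fraction)` samples are cases —
#' so the canonical 28/28 design is reproduced, not merely expected. High
#' neuropathology (NIARI) is assigned to the AD cases.
#'
#' Per-chromosome allele columns (`hap1_*`, `hap2_*`) record the simulation
#' truth (phase); they are not part of an observed sample sheet and exist so
#' that downstream expression simulation can tie allelic effects to the
#' haplotype that carries them.
#'
#' @param n Number of samples (>= 1).
#' @param haplotype_model A `haplotype_model` from [haplotype_frequencies()].
#' @param reporter_maf Frequency of the reporter G allele (0-1).
#' @param ad_fraction Fraction of AD cases; the split is exact.
#' @param seed Integer seed; fixed seed gives identical tables.
#' @return A data.frame with one row per sample: identifiers, the three
#'   genotypes, `niari`, `ad_status`, `sex`, `age_years`, `pmi_hours`, and the
#'   phased truth columns.
#' @export
simulate_cohort <- function(n, haplotype_model, reporter_maf = 0.45,
                            ad_fraction = 0.5, seed = 1L) {
  abort_if(n < 1, "n must be >= 1")
  abort_if(ad_fraction < 0 || ad_fraction > 1, "ad_fraction must lie in [0, 1]")
  abort_if(reporter_maf < 0 || reporter_maf > 1, "reporter_maf must lie in [0, 1]")
  stopifnot(inherits(haplotype_model, "haplotype_model"))

  with_seed(seed, {
    # haplotype index 1..4 = mm, mM, Mm, MM (first letter = rs35349669)
    h1 <- draw_haplotypes(haplotype_model, n)
    h2 <- draw_haplotypes(haplotype_model, n)
    a_minor <- snp_alleles$rs35349669["minor"]; a_major <- snp_alleles$rs35349669["major"]
    b_minor <- snp_alleles$rs10933431["minor"]; b_major <- snp_alleles$rs10933431["major"]
    hap_a <- function(h) ifelse(h <= 2L, a_minor, a_major)
    hap_b <- function(h) ifelse(h %in% c(1L, 3L), b_minor, b_major)

    rep1 <- ifelse(stats::runif(n) < reporter_maf, "G", "A")
    rep2 <- ifelse(stats::runif(n) < reporter_maf, "G", "A")

    n_ad <- round(n * ad_fraction)
    ad <- rep("non-AD", n)
    ad[sample.int(n, n_ad)] <- "AD"

    age <- round(stats::rnorm(n, 82, 7))
    pmi <- pmax(0.5, stats::rnorm(n, ifelse(ad == "AD", 3.4, 2.8),
                                  ifelse(ad == "AD", 0.6, 0.9)))

    data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      genotype_rs35349669 = mapply(canon_genotype, hap_a(h1), hap_a(h2),
                                   MoreArgs = list(snp = "rs35349669")),
      genotype_rs10933431 = mapply(canon_genotype, hap_b(h1), hap_b(h2),
                                   MoreArgs = list(snp = "rs10933431")),
      genotype_rs1141328 = mapply(canon_genotype, rep1, rep2,
                                  MoreArgs = list(snp = "rs1141328")),
      niari = ifelse(ad == "AD", "high", "low"),
      ad_status = ad,
      sex = sample(c("M", "F"), n, replace = TRUE),
      age_years = age,
      pmi_hours = round(pmi, 1),
      hap1_rs35349669 = unname(hap_a(h1)),
      hap2_rs35349669 = unname(hap_a(h2)),
      hap1_rs1141328 = rep1,
      hap2_rs1141328 = rep2,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}

#' Genotype-count fixture: the 3 x 3 AD-SNP genotype table
#'
#' A fixed 3x3 matrix of sample counts by rs10933431 genotype (rows GG, GC, CC)
#' and rs35349669 genotype (columns TT, TC, CC), reproducing the genotype
#' distribution of the brain cohort this package models. The table covers 61
#' genotyped individuals; it is a distinct artifact from the 56-sample
#' expression cohort ([fixture_cohort()]) and the two are deliberately not
#' reconciled.
#'
#' @return Integer matrix with dimnames rs10933431 x rs35349669.
#' @export
fixture_genotype_counts <- function() {
  m <- matrix(c(0L, 2L, 2L,
                1L, 15L, 7L,
                10L, 19L, 5L),
              nrow = 3, byrow = TRUE,
              dimnames = list(rs10933431 = c("GG", "GC", "CC"),
                              rs35349669 = c("TT", "TC", "CC")))
  m
}

#' Per-sample expansion of the genotype-count fixture
#'
#' One row per genotyped individual (61 rows), with the two AD-SNP genotype
#' columns, expanded from [fixture_genotype_counts()] in fixed row-major order.
#' Bit-identical across calls.
#'
#' @return data.frame with `sample_id`, `genotype_rs35349669`,
#'   `genotype_rs10933431`.
#' @export
fixture_genotype_table <- function() {
  counts <- fixture_genotype_counts()
  rows <- expand.grid(rs10933431 = rownames(counts),
                      rs35349669 = colnames(counts),
                      stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$rs10933431, rownames(counts)),
                     match(rows$rs35349669, colnames(counts))), ]
  reps <- counts[cbind(rows$rs10933431, rows$rs35349669)]
  out <- data.frame(
    genotype_rs10933431 = rep(rows$rs10933431, reps),
    genotype_rs35349669 = rep(rows$rs35349669, reps),
    stringsAsFactors = FALSE
  )
  out <- data.frame(sample_id = sprintf("G%03d", seq_len(nrow(out))),
                    genotype_rs35349669 = out$genotype_rs35349669,
                    genotype_rs10933431 = out$genotype_rs10933431,
                    stringsAsFactors = FALSE)
  out
}

#' Expression-cohort fixture: 56 samples with the reporter-SNP AEI subset
#'
#' A fixed 56-sample cohort table reproducing the composition of the modelled
#' expression study: 28 AD cases (12 male, 16 female) and 28 non-AD controls
#' (14 male, 14 female); 26 rs1141328 heterozygotes available for AEI, made up
#' of 11 AD (5 male, 6 female) and 15 non-AD (8 male, 7 female). High NIARI
#' neuropathology coincides with AD status. AD-SNP genotypes are a synthetic
#' deterministic assignment in the fixture-table proportions (the published
#' per-sample genotype-to-phenotype linkage is not available); ages and
#' post-mortem intervals are fixed values around the study means (AD 82 y,
#' PMI 3.4 h; non-AD 82 y, PMI 2.8 h). Bit-identical across calls.
#'
#' @return data.frame with the same observable columns as [simulate_cohort()]
#'   (no phase columns).
#' @export
fixture_cohort <- function() {
  sex <- c(rep("M", 12), rep("F", 16), rep("M", 14), rep("F", 14))
  ad <- c(rep("AD", 28), rep("non-AD", 28))
  # reporter heterozygosity by stratum: AD-M 5/12, AD-F 6/16, C-M 8/14, C-F 7/14
  het <- logical(56)
  het[1:5] <- TRUE      # AD male heterozygotes
  het[13:18] <- TRUE    # AD female heterozygotes
  het[29:36] <- TRUE    # non-AD male heterozygotes
  het[43:49] <- TRUE    # non-AD female heterozygotes
  g_rep <- ifelse(het, "GA", rep_len(c("GG", "AA"), 56))

  # deterministic AD-SNP genotype assignment scaled from the genotype table
  combos <- expand.grid(g10 = c("GG", "GC", "CC"), g35 = c("TT", "TC", "CC"),
                        stringsAsFactors = FALSE)
  counts56 <- c(GG_TT = 0, GC_TT = 1, CC_TT = 9,
                GG_TC = 2, GC_TC = 14, CC_TC = 17,
                GG_CC = 2, GC_CC = 6, CC_CC = 5)
  g35 <- rep(combos$g35, counts56)
  g10 <- rep(combos$g10, counts56)
  # interleave assignment across the AD/non-AD blocks deterministically
  ord <- order(rep_len(seq_len(8), 56), seq_len(56))
  age <- 82 + rep_len(c(-2L, 0L, 3L, -1L, 1L, 0L, -3L, 2L), 56)
  pmi <- ifelse(ad == "AD", 3.4, 2.8) + rep_len(c(-0.4, 0, 0.4, 0.2, -0.2), 56)

  data.frame(
    sample_id = sprintf("C%03d", seq_len(56)),
    genotype_rs35349669 = g35[ord],
    genotype_rs10933431 = g10[ord],
    genotype_rs1141328 = g_rep,
    niari = ifelse(ad == "AD", "high", "low"),
    ad_status = ad,
    sex = sex,
    age_years = age,
    pmi_hours = round(pmi, 1),
    stringsAsFactors = FALSE
  )
}

#' Load the packaged reference tables (genotype table and cohort table)
#'
#' Convenience wrapper returning both fixtures; see [fixture_genotype_table()]
#' and [fixture_cohort()]. They describe overlapping but non-identical sample
#' sets (61 genotyped vs 56 expression-profiled individuals) and are kept as
#' separate artifacts.
#'
#' @return list with elements `genotype_table` (61 rows), `genotype_counts`
#'   (3x3 matrix) and `cohort` (56 rows).
#' @export
load_reference_fixture <- function() {
  list(genotype_table = fixture_genotype_table(),
       genotype_counts = fixture_genotype_counts(),
       cohort = fixture_cohort())
}
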