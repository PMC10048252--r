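---
title: "Methods: allelic expression imbalance and isoform quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic expression imbalance and isoform quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconAEI)
```

This vignette documents the models implemented by `ampliconAEI`, the
assumptions behind them, the knobs a user can turn, and the design choices
made where the underlying experimental literature leaves the procedure open.

## The scientific setting

A gene's two alleles can produce unequal amounts of mRNA in the same nucleus
when a *cis*-acting regulatory variant sits on one haplotype. Measuring this
allelic expression imbalance (AEI) inside each heterozygous individual
removes all *trans* and environmental variation that plagues between-person
expression comparisons. The package models the canonical design: a
transcribed reporter SNP (rs1141328, 5'UTR, alleles G/A) tags each
transcript's haplotype of origin; targeted PCR amplicons from cDNA and from
genomic DNA (gDNA) are deep-sequenced; reads are assigned to alleles; and
candidate regulatory SNPs (rs35349669, rs10933431) are tested for
association with the imbalance. In parallel, isoform-specific qPCR assays
quantify the gene's transcription-start-site (TSS) isoforms and two
deletion variants against a microglial reference gene, as a function of
Alzheimer's-disease neuropathology (the NIARI low/high classification) and
genotype.

## Allele counting

`parse_allele_kmer()` expands a bracket spec (`"GCCGGCCC[G/A]GCCGAGG"`) into
the two allele-discriminating k-mers. `count_alleles()` assigns a read to an
allele when any window of the read — or of its reverse complement, since
amplicons are sequenced in both orientations — matches that allele's k-mer.

Matching policy. The default is exact matching (`max_mismatch = 0`), the
strictest reading of a 16-mer lookup; an optional one-mismatch mode is
provided for error tolerance. In mismatch mode the variant base itself must
always match exactly: forgiving a mismatch at the SNP position would let a
single sequencing error convert one allele into a near-match of the other
and bias the ratio. A read qualifying for both alleles (possible only with
mismatches or repeats) is counted once as *ambiguous*, never twice; reads
matching neither are *unassigned*. The four categories always sum to the
input read count, an invariant asserted on every call.

With exact matching, a read whose 16-mer was hit by a sequencing error is
simply unassigned. This loses a calculable fraction of depth
(`1 − (1−e)^16`, about 7.7% at `e = 0.005`) but loses it symmetrically, so
the allelic ratio is unbiased — the property the gDNA control verifies.

`allelic_ratio()` reports G:A (allele 1 = G by convention). Samples with
assigned depth below `min_depth` (default 100 reads; no published per-sample
filter exists, so the value is explicit and configurable) are flagged out of
downstream statistics. A zero denominator raises an error rather than
returning infinity.

## The AEI statistic

gDNA carries the two alleles 1:1, so its measured ratio captures
amplification and counting bias. `normalize_to_gdna()` divides each cDNA
ratio by the mean of the gDNA ratios (`cohort_mean`, the default, matching a
design that reports one gDNA control mean) or by the sample's own gDNA ratio
(`paired`). The per-sample statistic is the absolute deviation from the
cohort mean of normalized ratios, `aei_magnitude()`. The anchor is the
empirical mean rather than the theoretical 1.0 because residual global bias
(e.g. a slightly unbalanced gDNA mean) shifts all samples together;
`anchor = 1` is available. Deviations from the mean sum to zero by
construction, asserted per run.

Magnitudes are compared between genotype groups with a two-sided
Mann–Whitney U test (`rank_sum_test()`): imbalance magnitudes are bounded,
skewed quantities for which a rank test is the field's standard choice, and
no direction is assumed. The exact null is used for tie-free samples with
`min(n1, n2) ≤ 10` and `n1 + n2 ≤ 30` (via the exact U distribution) and for
tied samples whenever the labeling space is enumerable (≤ 2×10^5 labelings,
full enumeration with midranks); otherwise the normal approximation with tie
and continuity correction is used. Continuous AEI magnitudes essentially
never tie, so in practice small strata always get an exact p value. No
multiple-testing correction is applied; p values are nominal.

## Conditional stratification

The two candidate SNPs are in weak LD (r² = 0.18), so a double heterozygote's
phase — risk alleles on the same or opposite chromosomes — is unknown, and
their allelic effects could cancel or add. `stratify_for_conditional_test()`
therefore tests each SNP only in samples homozygous at the other: both of a
conditioning-homozygote's chromosomes carry the same conditioning allele, so
any imbalance difference between test-SNP heterozygotes and homozygotes
(both homozygote classes pooled) is attributable to the test SNP. Double
heterozygotes are excluded from both tests by this construction. On the
packaged 61-sample genotype table the strata are 17 homozygous vs 21
heterozygous for rs35349669 (among rs10933431 homozygotes) and 17 vs 8 for
rs10933431.

## qPCR quantitation and expression models

`fit_standard_curve()` fits Cq on log10(copies) by least squares; the
efficiency is `10^(−1/slope) − 1` and curves with non-negative slope are
flagged rejected. `cq_to_copies()` inverts the curve; sub-single-copy
results are returned but flagged below range. Replicate Cq values are
averaged before quantitation (replicate handling is otherwise unspecified in
the motivating design).

`fit_expression_model()` regresses the log10 target copies on z-scored
predictors — log10 reference copies, a 0/1 NIARI indicator, genotype dose —
with the response z-scored too, so coefficients are standardized betas and a
sole predictor's beta equals its Pearson correlation (asserted to 1e-12 in
the tests). Log base 10 is used throughout; the base cancels out of
standardized coefficients, so this is a display convention. The reference
gene enters as a covariate rather than by pre-dividing, which keeps its own
measurement error in the model; ratio-based analyses (isoform relative to
full-length) are supported through `relative_expression()`. Genotype coding
is additive minor-allele dose by default with dominant and recessive options,
since no coding is canonical. Rank-deficient designs and constant predictors
are errors that name the offending columns.

`chx_trend()` summarizes a cycloheximide time course by the least-squares
slope of the decay-sensitive splice fraction on hours within the CHX arm,
the contrast against the vehicle arm's slope (interaction p), and a Spearman
rank correlation as a distribution-free alternative — the experimental claim
being only that the fraction *rises* with treatment time when NMD is
blocked.

## The isoform catalog

Transcripts live in 1-based, closed, spliced coordinates; exons follow the
full-length reference transcript's global numbering (ex1–ex27), and
intron-derived first exons are labelled `inN` (the TSS-C isoform 213 starts
in intron 14 — the catalog consistently anchors its assay at intron 14, and
identifies the phosphatase-only isoform as 213 throughout). A primer pair
captures an isoform when the isoform contains both anchor units and no exon
of the global numbering between them is absent; intron-derived units between
anchors do not count, since they are spliced out of most isoforms. On the
packaged catalog this reproduces the five assay capture sets
(`capture_table()`) and the TSS map A→{201, 204, 205}, B→{202}, C→{213}.

The packaged sequences are **synthetic**: real genomic sequence is not
shipped, and `read_catalog()` loads user catalogs with real sequences. The
synthetic sequences are engineered so the two biologically important derived
variants behave as annotated in the field: deleting the first 47 nt of
exon 12 (D47; 47 mod 3 = 2) frameshifts into a premature termination codon
(PTC) far upstream of the last junction, and skipping exon 26 (D26)
frameshifts the terminal exon into the 17-residue carboxyl tail
SEALSELPLSREPRGTA ending within the last exon. The tail peptide is also
stored as a catalog annotation so the tail-extraction code path is testable
against an independent record. Exon lengths are toy values chosen so the
documented diagnostic amplicons come out at their published sizes (an
exon-9-to-exon-12 product of 458 nt whose D47 counterpart is 411 nt).

`annotate_orf()` translates from the CDS start to the first stop and
compares against the reference protein: the frameshift flag is exactly
(deletion length mod 3 ≠ 0) for simple deletions, the novel tail is the
residue run after the longest common prefix with the reference, and a stop
is premature only for deletion-derived variants that terminate before their
reference (natural isoforms that merely start downstream, like the exon-11
TSS-B isoform, are not PTC-bearing). `nmd_candidate()` applies the classic
junction rule — a PTC more than 50 nt (configurable) upstream of the final
exon–exon junction triggers decay — with a strict inequality at the
boundary, returning FALSE for last-exon PTCs and single-exon transcripts.

## The synthetic-data generator

The generator's defaults encode the modelled study's conditions.

* **Haplotypes** (`haplotype_frequencies()`): minor-allele frequencies 0.498
  and 0.220 with r² = 0.18. r² is sign-free, so a coupling convention is
  required: by default D > 0 (minor alleles co-occur), with `d_sign = -1` to
  flip. Infeasible r² requests fail with the achievable maximum named.
* **Cohorts** (`simulate_cohort()`): two independent haplotypes per sample,
  an unlinked reporter SNP (frequency of G defaulting to 0.45, giving about
  half the cohort heterozygous, as in the modelled 26-of-56 subset), and an
  *exact* `round(n × ad_fraction)` AD split — the 28/28 design is a design,
  not a coin flip. High NIARI coincides with AD status, and NIARI is
  independent of genotype. Phased truth columns (`hap1_*`, `hap2_*`) ride
  along for the expression simulator.
* **Expression** (`simulate_expression()`): log-normal copies tracking the
  reference gene (so isoform–reference correlations are strong, as real
  bulk-tissue microglial markers are), per-assay NIARI fold effects
  (defaults between 1.3 and 2.0, modest multiplicative effects of high
  pathology), and a D47 fraction logit-normal around a mean of 0.13 — the
  share of exon-12-containing transcripts carried by the deletion isoform.
  The allelic effect is mechanistic: each chromosome carrying the
  rs35349669 minor allele transcribes `aei_effect` times the base rate
  (default 1.1; sign flippable), so only test-SNP heterozygotes show
  imbalance and the measured G:A ratio follows the reporter allele's phase.
  The direction default (minor allele increases expression) follows public
  expression-QTL resources for this gene; it is a convention, not a claim.
* **Reads** (`simulate_amplicon_reads()`): barcode + fixed flank + allele
  k-mer + flank, 250 nt (2×250 amplicon sequencing), per-read allele chosen
  Bernoulli from the true ratio (0.5 for gDNA), substitution-only uniform
  errors. Paired-end overlap, adapters, quality decay, PCR duplicates and
  chimeras are out of scope; qualities are constant Phred+33.
* **qPCR plates** (`simulate_qpcr_plate()`): Cq = intercept + slope·log10
  copies + Normal(0, `qpcr_sd` = 0.15 Cq), with a 10-fold dilution series in
  duplicate per assay for curve refitting.
* **CHX time course** (`simulate_chx_timecourse()`): 1/3/5/8 h in
  triplicate; CHX arm rises `baseline + increment × hours` (defaults 0.13 +
  0.02/h), vehicle flat, fractions truncated to [0, 1].

Everything is driven by one integer seed; `derive_seed()` gives each stage a
named substream so stages are independently reproducible and a fixed seed
yields byte-identical FASTQ output.

What passing tests show — and what they do not. The generator reproduces the
*statistical structure* the analyses assume: HWE genotypes with the stated
LD, binomial allele sampling, log-normal expression, log-linear qPCR. Real
data add haplotype structure beyond two SNPs, PCR jackpot effects,
overdispersed allele counts, batch effects and cell-type composition shifts;
a pipeline validated here is correctly *implemented*, not guaranteed
well-calibrated on real tissue.

## Numerical choices and degenerate inputs

* Haplotype frequencies reproduce requested marginals and r² to 1e-9;
  boundary MAFs (0 or 1) are accepted only with r² = 0.
* Empty read sets count to all-zero (not an error); k-mer longer than the
  read errors.
* The packaged reference tables are two distinct artifacts — a 61-sample
  genotype table and a 56-sample expression cohort — deliberately not
  reconciled, mirroring a genotyping set that is larger than the expression
  set. The cohort fixture's AD-SNP genotype assignment is a synthetic
  deterministic scaling of the genotype table (the real per-sample linkage
  is not public).
* Exact rank-sum p values use the symmetric deviation-of-U definition
  (`P(|U − n1n2/2| ≥ |u − n1n2/2|)`); with heavy ties and large samples the
  enumeration becomes infeasible and the implementation deliberately falls
  back to the tie-corrected normal approximation even inside the nominal
  "exact" size range.
* Standard-curve R² is computed from residuals directly so noise-free
  dilution series do not trigger spurious perfect-fit warnings; the
  round-trip Cq→copies error on noise-free input is below 1e-9 relative.

## Problem sizes used by the test suite

The suite exercises: cohorts of 56 (the modelled design) up to 10,000 (HWE
checks); read sets of 200–10,000 reads; 1,000 null cohorts for the
conditional test's type-I error (0.05 ± 0.02 at α = 0.05); 500 seeds for
NIARI effect-sign recovery at fold 1.5; and 26 × 10,000-read gDNA simulations
for the balanced-control benchmark. These sizes give stable Monte-Carlo
estimates while keeping the full suite around a minute of compute.

## Known limitations

No haplotype phasing, no beta-binomial overdispersion model for per-sample
imbalance, no covariate-adjusted AEI regression, no genome alignment or
splice-site prediction, and no ΔΔCq or multi-reference qPCR normalization.
The expression models include reference expression, NIARI and genotype;
age, sex and post-mortem interval are carried in the cohort tables but not
entered as covariates by default.
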