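Package: ampliconAEI
Title: Allelic Expression Imbalance and Isoform Quantitation for Amplicon
    and qPCR Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying allele-specific gene expression from
    targeted amplicon sequencing and for isoform-level expression analysis by
    qPCR, modelled on allelic expression imbalance (AEI) studies of the
    microglial gene INPP5D in post-mortem brain. Includes bracket-notation
    reporter-SNP k-mer parsing and allele counting with reverse-complement and
    mismatch policies, genomic-DNA normalization of allelic ratios, conditional
    genotype-stratified rank-sum tests, standard-curve qPCR quantitation with
    neuropathology/genotype linear models, a transcript-isoform catalog with
    primer capture-set algebra and frameshift/premature-termination-codon/
    nonsense-mediated-decay annotation of deletion variants, and a synthetic
    data generator (linkage-disequilibrium haplotype cohorts, allele-specific
    reads, qPCR plates, cycloheximide time courses) reproducing the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
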