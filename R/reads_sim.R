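# Allele-specific amplicon read simulation and FASTQ input/output.

# Fixed amplicon flanking sequences around the embedded reporter k-mer.
# These are documented constants of the simulator (chosen once, free of both
# allele k-mers and their reverse complements); reads are
# barcode + left flank + allele k-mer + right flank, trimmed to read_length.
AMPLICON_FLANK_LEFT <- paste0(
  "CCTGAATCGTGTATAAGGCGCGCTAGTACCCGGCCCCTTAGTTCTAGGACGTACCCCACAG",
  "AGCTCCACCGCCTGAAACTGTATGCTGGCCCCTCCTCCCTGCGTACGTT")
AMPLICON_FLANK_RIGHT <- paste0(
  "GGGTGCTAGATGATAGCGGATGATTCGAGACGGAGGTGGATTTGGCAATTTCAGTTCGGTACTCAAGATA",
  "TCATTTCTTCTGACCCTAAGGGCAACACTGTGGGGAGCGTTATCGGGCTACTACACTTGGCCTGGTACTC",
  "TCCGTGGCCT")

DNA_BASES <- c("A", "C", "G", "T")

#' Simulate amplicon reads for one sample and material
#'
#' Each of `depth` reads embeds one allele k-mer inside fixed flanking
#' sequence, with the barcode prepended. For cDNA from reporter heterozygotes
#' the per-read allele-1 probability is `r / (1 + r)` where `r` is the true
#' allelic ratio; genomic DNA heterozygotes are unbiased (p = 0.5); reporter
#' homozygotes get p of 0 or 1. Uniform per-base substitution errors are then
#' applied across the whole read (barcode included). Substitution-only,
#' position-uniform error; paired-end structure, adapters and quality decay
#' are not modelled.
#'
#' @param sample One-row cohort data.frame (needs `sample_id`,
#'   `genotype_rs1141328`).
#' @param material `"cDNA"` or `"gDNA"`.
#' @param expression_state One-row data.frame from [simulate_expression()]
#'   (needs `allelic_ratio_true`); may be NULL for gDNA.
#' @param kmer_pair An [parse_allele_kmer()] pair; allele 1 is the G allele.
#' @param depth Number of reads (> 0).
#' @param error_rate Per-base substitution probability.
#' @param barcode Barcode string prepended to every read.
#' @param seed Integer seed; fixed seed gives byte-identical reads.
#' @param read_length Total read length (default 250, as produced by 2x250
#'   amplicon sequencing).
#' @return data.frame of class `read_set`: `read_id`, `seq`, `qual`.
#' @export
simulate_amplicon_reads <- function(sample, material, expression_state,
                                    kmer_pair, depth, error_rate = 0,
                                    barcode = "ACGTACGT", seed = 1L,
                                    read_length = 250L) {
  abort_if(!material %in% c("cDNA", "gDNA"),
           "unknown material label '%s' (expected cDNA or gDNA)", material)
  abort_if(depth <= 0, "depth must be positive")
  stopifnot(inherits(kmer_pair, "allele_kmer_pair"))

  geno <- sample$genotype_rs1141328
  a1 <- kmer_pair$allele_labels[1]  # G by convention
  a2 <- kmer_pair$allele_labels[2]
  n1 <- sum(strsplit(geno, "")[[1]] == a1)
  p <- if (n1 == 2) 1 else if (n1 == 0) 0 else if (material == "gDNA") {
    0.5
  } else {
    r <- expression_state$allelic_ratio_true
    abort_if(is.null(r) || is.na(r),
             "cDNA simulation for a heterozygote needs allelic_ratio_true")
    r / (1 + r)
  }

  template <- paste0(barcode, AMPLICON_FLANK_LEFT)
  snp_pos <- nchar(template) + kmer_pair$snp_offset + 1L  # 1-based in read
  template <- paste0(template, kmer_pair$kmer_allele1, AMPLICON_FLANK_RIGHT)
  template <- substr(template, 1L, read_length)
  abort_if(nchar(template) < snp_pos,
           "read_length %d too short to contain the k-mer", read_length)
  L <- nchar(template)

  with_seed(seed, {
    use_a1 <- stats::runif(depth) < p
    tchars <- strsplit(template, "")[[1]]
    m <- matrix(tchars, nrow = L, ncol = depth)
    m[snp_pos, !use_a1] <- a2
    if (error_rate > 0) {
      n_err <- stats::rbinom(1, L * depth, error_rate)
      if (n_err > 0) {
        pos <- sample.int(L * as.integer(depth), n_err)
        idx <- match(m[pos], DNA_BASES)
        m[pos] <- DNA_BASES[((idx - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L) + 1L]
      }
    }
    seqs <- apply(m, 2, paste, collapse = "")
    out <- data.frame(
      read_id = sprintf("%s:%s:%06d", sample$sample_id, material, seq_len(depth)),
      seq = seqs,
      qual = strrep("I", L),
      stringsAsFactors = FALSE
    )
    class(out) <- c("read_set", class(out))
    out
  })
}

#' Write reads as a FASTQ file
#'
#' Four-line records with Phred+33 qualities (constant by default). Writing is
#' plain-text and byte-deterministic.
#'
#' @param reads A `read_set` data.frame (`read_id`, `seq`, optional `qual`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% strrep("I", nchar(reads$seq))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual)),
             con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file (plain or gzipped)
#'
#' Parsed with [Biostrings::readDNAStringSet()]; returns the same `read_set`
#' shape the simulator produces.
#'
#' @param path FASTQ path (`.gz` accepted).
#' @return data.frame of class `read_set`: `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- data.frame(read_id = names(x), seq = as.character(x),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("read_set", class(out))
  out
}
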