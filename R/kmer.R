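# Reporter-SNP k-mer parsing, barcode demultiplexing and allele counting.

#' Parse a bracket-notation reporter-SNP k-mer specification
#'
#' A spec like `"GCCGGCCC[G/A]GCCGAGG"` expands into the two
#' allele-discriminating k-mers (here 16-mers), recording the 0-based offset
#' of the variant base and the single-base allele labels. Exactly one
#' `[X/Y]` block with two distinct single bases is required; flanks must be
#' plain A/C/G/T.
#'
#' @param spec Bracket-notation string.
#' @return Object of class `allele_kmer_pair`: `kmer_allele1`, `kmer_allele2`,
#'   `snp_offset` (0-based), `k`, `allele_labels`.
#' @examples
#' parse_allele_kmer("GCCGGCCC[G/A]GCCGAGG")
#' @export
parse_allele_kmer <- function(spec) {
  abort_if(!is.character(spec) || length(spec) != 1, "spec must be one string")
  n_open <- lengths(regmatches(spec, gregexpr("\\[", spec)))
  abort_if(n_open == 0, "no [X/Y] allele block found in '%s'", spec)
  abort_if(n_open > 1, "multiple allele blocks found in '%s'; exactly one is allowed", spec)
  m <- regexec("^([ACGT]*)\\[([ACGT])/([ACGT])\\]([ACGT]*)$", spec)
  parts <- regmatches(spec, m)[[1]]
  abort_if(length(parts) == 0,
           "malformed spec '%s': flanks must be A/C/G/T and the block must be [X/Y] with single bases",
           spec)
  left <- parts[2]; x <- parts[3]; y <- parts[4]; right <- parts[5]
  abort_if(x == y, "allele block [%s/%s] lists identical alleles", x, y)
  structure(list(
    kmer_allele1 = paste0(left, x, right),
    kmer_allele2 = paste0(left, y, right),
    snp_offset = nchar(left),
    k = nchar(left) + 1L + nchar(right),
    allele_labels = c(x, y)
  ), class = "allele_kmer_pair")
}

#' @export
print.allele_kmer_pair <- function(x, ...) {
  cat(sprintf("Allele k-mer pair (k = %d, SNP offset %d, alleles %s/%s)\n  %s\n  %s\n",
              x$k, x$snp_offset, x$allele_labels[1], x$allele_labels[2],
              x$kmer_allele1, x$kmer_allele2))
  invisible(x)
}

#' Demultiplex reads by barcode prefix
#'
#' Matches each read's leading bases against the barcode map (optionally
#' tolerating up to `max_barcode_mismatch` substitutions), trims the barcode,
#' and partitions reads into per-sample buckets plus an unassigned pool. The
#' map must be unambiguous: pairwise barcode Hamming distance greater than
#' twice the tolerated mismatch.
#'
#' @param reads `read_set` data.frame (or character vector of sequences).
#' @param barcode_map Named character vector: names are sample labels, values
#'   barcodes (equal length).
#' @param max_barcode_mismatch Allowed substitutions in the barcode (default 0).
#' @return List with one `read_set` per sample label (barcodes trimmed) and an
#'   `unassigned` read set.
#' @export
demultiplex <- function(reads, barcode_map, max_barcode_mismatch = 0L) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = sprintf("r%06d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  }
  bl <- unique(nchar(barcode_map))
  abort_if(length(bl) != 1, "barcodes must all have the same length")
  abort_if(anyDuplicated(barcode_map) > 0, "duplicate barcodes in map")
  if (length(barcode_map) > 1) {
    d <- utils::combn(barcode_map, 2, function(p) hamming(p[1], p[2]))
    abort_if(min(d) <= 2 * max_barcode_mismatch,
             "ambiguous barcode map: minimum pairwise Hamming distance %d does not exceed 2 x max mismatch (%d)",
             min(d), as.integer(2 * max_barcode_mismatch))
  }
  prefix <- substr(reads$seq, 1L, bl)
  assign <- rep(NA_integer_, nrow(reads))
  if (max_barcode_mismatch == 0) {
    assign <- match(prefix, barcode_map)
  } else {
    pm <- do.call(rbind, strsplit(prefix, "", fixed = TRUE))
    for (i in seq_along(barcode_map)) {
      bc <- strsplit(barcode_map[[i]], "", fixed = TRUE)[[1]]
      mm <- rowSums(pm != matrix(bc, nrow(pm), bl, byrow = TRUE))
      assign[mm <= max_barcode_mismatch] <- i
    }
  }
  out <- lapply(seq_along(barcode_map), function(i) {
    sub <- reads[!is.na(assign) & assign == i, , drop = FALSE]
    sub$seq <- substr(sub$seq, bl + 1L, nchar(sub$seq))
    rownames(sub) <- NULL
    sub
  })
  names(out) <- names(barcode_map)
  una <- reads[is.na(assign), , drop = FALSE]
  rownames(una) <- NULL
  out$unassigned <- una
  out
}

# windows of `read` matching `kmer` with <= max_mismatch substitutions outside
# the SNP base and an exact SNP base; returns TRUE if any window qualifies
.kmer_hits <- function(seqs, kmer, snp_offset, allele, max_mismatch) {
  if (max_mismatch == 0) return(grepl(kmer, seqs, fixed = TRUE))
  subj <- Biostrings::DNAStringSet(seqs)
  mt <- Biostrings::vmatchPattern(kmer, subj, max.mismatch = max_mismatch,
                                  fixed = TRUE)
  starts <- Biostrings::startIndex(mt)
  hit <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    st <- starts[[i]]
    if (is.null(st) || length(st) == 0) next
    st <- st[st >= 1 & st + nchar(kmer) - 1 <= nchar(seqs[i])]
    if (length(st) == 0) next
    snp_base <- substring(seqs[i], st + snp_offset, st + snp_offset)
    hit[i] <- any(snp_base == allele)
  }
  hit
}

#' Count reporter-SNP alleles in a read set
#'
#' A read is assigned to an allele when any window of the read (or of its
#' reverse complement, when `allow_revcomp`) matches that allele's k-mer
#' within `max_mismatch` substitutions, with the variant base itself required
#' to match exactly (a mismatch at the SNP position is never forgiven, so
#' sequencing errors cannot silently convert one allele into a near-match of
#' the other). Reads qualifying for both alleles are counted once as
#' ambiguous, reads matching neither as unassigned; the four categories
#' always sum to the input read count.
#'
#' @param read_set `read_set` data.frame or character vector of sequences.
#' @param kmer_pair [parse_allele_kmer()] result.
#' @param allow_revcomp Also scan the reverse-complement orientation
#'   (default TRUE; amplicons are sequenced in both orientations).
#' @param max_mismatch 0 (exact, default) or 1.
#' @param sample_id,material Labels carried into the result.
#' @return Object of class `allele_counts`: a one-row data.frame with
#'   `sample_id`, `material`, `n_allele1`, `n_allele2`, `n_ambiguous`,
#'   `n_unassigned`, `n_total`.
#' @export
count_alleles <- function(read_set, kmer_pair, allow_revcomp = TRUE,
                          max_mismatch = 0L, sample_id = NA_character_,
                          material = NA_character_) {
  stopifnot(inherits(kmer_pair, "allele_kmer_pair"))
  abort_if(!max_mismatch %in% c(0L, 1L), "max_mismatch must be 0 or 1")
  seqs <- if (is.character(read_set)) read_set else read_set$seq
  if (length(seqs) > 0) {
    abort_if(kmer_pair$k > min(nchar(seqs)),
             "k-mer length %d exceeds the shortest read (%d nt)",
             kmer_pair$k, min(nchar(seqs)))
  }
  k <- kmer_pair$k
  hit_allele <- function(kmer, allele) {
    h <- .kmer_hits(seqs, kmer, kmer_pair$snp_offset, allele, max_mismatch)
    if (allow_revcomp) {
      rk <- revcomp(kmer)
      # on the reverse strand the SNP base sits mirrored at the complementary
      # offset with the complementary allele
      h <- h | .kmer_hits(seqs, rk, k - 1L - kmer_pair$snp_offset,
                          revcomp(allele), max_mismatch)
    }
    h
  }
  h1 <- hit_allele(kmer_pair$kmer_allele1, kmer_pair$allele_labels[1])
  h2 <- hit_allele(kmer_pair$kmer_allele2, kmer_pair$allele_labels[2])

  out <- data.frame(
    sample_id = sample_id, material = material,
    n_allele1 = sum(h1 & !h2), n_allele2 = sum(h2 & !h1),
    n_ambiguous = sum(h1 & h2), n_unassigned = sum(!h1 & !h2),
    stringsAsFactors = FALSE
  )
  out$n_total <- out$n_allele1 + out$n_allele2 + out$n_ambiguous + out$n_unassigned
  stopifnot(out$n_total == length(seqs))
  class(out) <- c("allele_counts", class(out))
  out
}

#' Allelic ratio (allele 1 : allele 2) from allele counts
#'
#' Ratio of assigned allele-1 to allele-2 reads, by convention G:A for the
#' reporter SNP. Samples whose assigned depth (`n_allele1 + n_allele2`) falls
#' below `min_depth` are flagged for exclusion from downstream statistics. A
#' zero allele-2 count is an explicit error rather than a silent infinity.
#'
#' @param counts One-row `allele_counts`.
#' @param min_depth Minimum assigned depth (default 100).
#' @return List: `ratio`, `depth`, `pass_depth`.
#' @export
allelic_ratio <- function(counts, min_depth = 100L) {
  abort_if(counts$n_allele2 == 0,
           "allelic ratio undefined: allele-2 count is zero (sample %s)",
           counts$sample_id)
  depth <- counts$n_allele1 + counts$n_allele2
  list(ratio = counts$n_allele1 / counts$n_allele2,
       depth = depth,
       pass_depth = depth >= min_depth)
}
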