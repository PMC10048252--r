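# Independent brute-force oracles used to cross-check package implementations.
# Deliberately written from first principles (no calls into the code paths
# they verify).

# reverse complement without Biostrings
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(strsplit(s, ""), function(x)
    paste(rev(x), collapse = ""), character(1)))
}

# naive all-window allele counting with the stated matching policy:
# a window matches allele i when its SNP base equals that allele exactly and
# the remaining positions differ from the allele k-mer in <= max_mismatch
# places; both strands scanned when revcomp = TRUE
oracle_count_alleles <- function(seqs, kmer1, kmer2, snp_offset,
                                 revcomp = TRUE, max_mismatch = 0) {
  k <- nchar(kmer1)
  k1 <- strsplit(kmer1, "")[[1]]
  k2 <- strsplit(kmer2, "")[[1]]
  match_one <- function(readchars, kchars) {
    n <- length(readchars)
    if (n < k) return(FALSE)
    for (st in 1:(n - k + 1)) {
      w <- readchars[st:(st + k - 1)]
      if (w[snp_offset + 1] != kchars[snp_offset + 1]) next
      mism <- sum(w != kchars) # SNP base already known equal
      if (mism <= max_mismatch) return(TRUE)
    }
    FALSE
  }
  hit <- function(s, kchars) {
    fw <- match_one(strsplit(s, "")[[1]], kchars)
    if (!revcomp) return(fw)
    fw || match_one(strsplit(oracle_revcomp(s), "")[[1]], kchars)
  }
  h1 <- vapply(seqs, hit, logical(1), kchars = k1, USE.NAMES = FALSE)
  h2 <- vapply(seqs, hit, logical(1), kchars = k2, USE.NAMES = FALSE)
  c(n_allele1 = sum(h1 & !h2), n_allele2 = sum(h2 & !h1),
    n_ambiguous = sum(h1 & h2), n_unassigned = sum(!h1 & !h2))
}

# exact two-sided rank-sum p by full enumeration of all group-1 labelings,
# using the symmetric deviation-of-U definition (tie-safe via midranks)
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# hand-coded standard-genetic-code translation, stops at first stop codon
oracle_translate <- function(cds) {
  codon_table <- c(
    TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  n <- floor(nchar(cds) / 3)
  aas <- codon_table[substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))]
  stop_at <- which(aas == "*")
  if (length(stop_at)) paste(aas[seq_len(stop_at[1] - 1)], collapse = "")
  else paste(aas, collapse = "")
}

# random read generator mixing background, embedded and mutated k-mers
random_reads <- function(n, kmer_pair, len = 40) {
  mk <- function() paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  vapply(seq_len(n), function(i) {
    base <- mk()
    kind <- sample(c("bg", "embed1", "embed2", "mut", "rc"), 1)
    if (kind == "bg") return(base)
    km <- if (kind == "embed2") kmer_pair$kmer_allele2 else kmer_pair$kmer_allele1
    if (kind == "mut") {
      pos <- sample(nchar(km), 1)
      substr(km, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(km, pos, pos)), 1)
    }
    if (kind == "rc") km <- oracle_revcomp(km)
    at <- sample(len - nchar(km) + 1, 1)
    paste0(substr(base, 1, at - 1), km,
           substr(base, at + nchar(km), len))
  }, character(1))
}

fixture_haplotype_model <- function() haplotype_frequencies(0.498, 0.220, 0.18)

# the read simulator's first RNG draw after seeding is the per-read allele
# Bernoulli; reproduce that draw to check lossless recovery
with_seed_count <- function(seed, depth, p) {
  set.seed(as.integer(seed))
  sum(stats::runif(depth) < p)
}
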