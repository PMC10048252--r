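#' Two-locus haplotype frequencies from marginal MAFs and LD r-squared
#'
#' Builds the four haplotype frequencies over \{minor, major\} x \{minor,
#' major\} for two biallelic SNPs from their minor-allele frequencies and the
#' squared LD correlation r2. r2 carries no sign, so a coupling convention must
#' be chosen: by default D > 0, i.e. the two minor alleles co-occur more often
#' than expected under independence (`d_sign = -1` flips this).
#'
#' The LD coefficient is `D = sign * sqrt(r2 * pA qA pB qB)` and the
#' minor-minor haplotype frequency is `pA pB + D`.
#'
#' @param maf_a,maf_b Minor-allele frequencies, strictly inside (0, 1).
#' @param r2 Squared LD correlation in `[0, 1]`.
#' @param d_sign +1 (default, minor alleles coupled) or -1.
#' @return An object of class `haplotype_model`: list with `maf_a`, `maf_b`,
#'   `r2`, `D`, and `haplotype_freqs` (named numeric of length 4:
#'   `mm`, `mM`, `Mm`, `MM`; first letter = SNP A allele, minor/Major).
#' @examples
#' haplotype_frequencies(0.498, 0.220, 0.18)
#' @export
haplotype_frequencies <- function(maf_a, maf_b, r2, d_sign = 1) {
  abort_if(maf_a < 0 || maf_a > 1 || maf_b < 0 || maf_b > 1,
           "MAFs must lie in [0, 1]; got %g and %g", maf_a, maf_b)
  abort_if(r2 < 0 || r2 > 1, "r2 must lie in [0, 1]; got %g", r2)
  abort_if(!d_sign %in% c(-1, 1), "d_sign must be +1 or -1")
  if (maf_a %in% c(0, 1) || maf_b %in% c(0, 1)) {
    # monomorphic locus: correlation is undefined, only r2 = 0 is coherent
    abort_if(r2 != 0, "r2 must be 0 when a locus is monomorphic")
    freqs <- c(mm = maf_a * maf_b, mM = maf_a * (1 - maf_b),
               Mm = (1 - maf_a) * maf_b, MM = (1 - maf_a) * (1 - maf_b))
    return(structure(list(maf_a = maf_a, maf_b = maf_b, r2 = 0, D = 0,
                          haplotype_freqs = freqs),
                     class = "haplotype_model"))
  }

  pA <- maf_a; qA <- 1 - maf_a
  pB <- maf_b; qB <- 1 - maf_b
  denom <- pA * qA * pB * qB
  # Lewontin bounds on D for the requested sign
  d_max <- if (d_sign > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  r2_max <- d_max^2 / denom
  abort_if(r2 > r2_max + 1e-12,
           "r2 = %g is not achievable for MAFs (%g, %g): maximum achievable r2 is %g",
           r2, maf_a, maf_b, r2_max)

  D <- d_sign * sqrt(r2 * denom)
  freqs <- c(
    mm = pA * pB + D,
    mM = pA * qB - D,
    Mm = qA * pB - D,
    MM = qA * qB + D
  )
  # clamp tiny negatives from floating point at the feasibility boundary
  freqs[freqs < 0 & freqs > -1e-12] <- 0
  structure(
    list(maf_a = maf_a, maf_b = maf_b, r2 = r2, D = D,
         haplotype_freqs = freqs),
    class = "haplotype_model"
  )
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf("Two-locus haplotype model: MAFs %.3f / %.3f, r2 = %.3f, D = %+.4f\n",
              x$maf_a, x$maf_b, x$r2, x$D))
  print(round(x$haplotype_freqs, 5))
  invisible(x)
}

# draw one haplotype index per row from the model's frequencies
draw_haplotypes <- function(model, n) {
  sample.int(4L, n, replace = TRUE, prob = model$haplotype_freqs)
}
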