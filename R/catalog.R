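# The packaged toy isoform catalog and catalog JSON input/output.
#
# The catalog reproduces the exon topology of the modelled gene's five
# annotated brain isoforms (full-length 201 and 204; SH2-only 205; the
# exon-11-start phosphatase isoform 202; the intron-14-start isoform 213)
# with SYNTHETIC nucleotide sequences: real genomic sequence is deliberately
# not shipped. Sequences are constructed so that the biologically relevant
# derived variants behave as annotated in the field:
#   * deleting the first 47 nt of exon 12 (D47) frameshifts and introduces a
#     premature termination codon well upstream of the last junction (an NMD
#     candidate);
#   * skipping exon 26 (D26) frameshifts into a novel 17-residue carboxyl
#     tail (SEALSELPLSREPRGTA) terminating within the last exon (not an NMD
#     candidate).
# A loader for user-supplied catalogs with real sequences is provided
# (read_catalog / write_catalog).

# codons free of stop codons, cycled as background CDS filler; the block's
# +2 frame contains TGA so any frameshift eventually terminates
SAFE_CODONS <- c("GCT", "GAA", "CTT", "TCC", "AAG", "GTG", "CAC", "ATC")

D26_NOVEL_TAIL <- "SEALSELPLSREPRGTA"

# greedy synonymous-codon choice for a peptide such that the frame-0 reading
# of (prefix + codons) contains no stop codon
.codons_for_tail <- function(peptide, prefix = "GC") {
  tab <- list(S = c("AGC", "TCC", "TCT"), E = c("GAA", "GAG"),
              A = c("GCT", "GCC", "GCA"), L = c("CTT", "CTG", "CTC"),
              P = c("CCT", "CCC", "CCA"), R = c("AGA", "CGT", "CGC"),
              G = c("GGT", "GGC", "GGA"), T = c("ACT", "ACC", "ACA"))
  has_stop0 <- function(s) {
    n <- floor(nchar(s) / 3)
    any(substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n)) %in%
          c("TAA", "TAG", "TGA"))
  }
  built <- prefix
  for (aa in strsplit(peptide, "")[[1]]) {
    ok <- FALSE
    for (cd in tab[[aa]]) {
      if (!has_stop0(paste0(built, cd, "X"))) { built <- paste0(built, cd); ok <- TRUE; break }
    }
    abort_if(!ok, "no stop-free codon choice for residue %s", aa)
  }
  substr(built, nchar(prefix) + 1, nchar(built))
}

#' Build the packaged toy isoform catalog
#'
#' Deterministic (no randomness): identical across calls. See the file-level
#' notes for what the synthetic sequences guarantee. Exon lengths are toy
#' values chosen so the documented diagnostic amplicons come out at their
#' published sizes (e.g. an exon-9-to-exon-12 product of 458 nt whose D47
#' counterpart is 411 nt).
#'
#' @return Object of class `isoform_catalog`: named `transcripts` list,
#'   `domains` (SH2 / phosphatase exon ranges), `primer_pairs` (the five
#'   isoform-discriminating capture pairs), `annotations` (includes the
#'   recorded D26 novel-tail peptide), `tss` (TSS label to first unit).
#' @export
toy_catalog <- function() {
  ex_len <- c(ex1 = 150, ex2 = 90, ex3 = 90, ex4 = 96, ex5 = 90, ex6 = 90,
              ex7 = 90, ex8 = 90, ex9 = 120, ex10 = 150, ex11 = 130,
              ex12 = 200, ex13 = 120, ex14 = 90, ex15 = 90, ex16 = 90,
              ex17 = 90, ex18 = 90, ex19 = 90, ex20 = 90, ex21 = 90,
              ex22 = 90, ex23 = 90, ex24 = 90, ex25 = 92, ex26 = 92,
              ex27 = 300)
  cds_start <- 101
  total <- sum(ex_len)

  # --- spliced sequence of the full-length reference (201) ---------------
  # 5'UTR: fixed filler with the reporter-SNP 16-mer (G allele) at 40..55
  utr <- strrep("TCAGCTAGGACTTGCACTGA", 5)            # 100 nt
  utr <- paste0(substr(utr, 1, 39), "GCCGGCCCGGCCGAGG", substr(utr, 56, 100))

  # CDS codons from position 101 up to the start of exon 27 (codon layout is
  # independent of exon boundaries; exon 27 is built explicitly below)
  ex27_start <- total - ex_len[["ex27"]] + 1          # 2681
  n_codons <- (ex27_start - cds_start) / 3            # 860, by construction
  stopifnot(n_codons == floor(n_codons))
  codons <- rep_len(SAFE_CODONS, n_codons)
  # junction codon spanning exon 25/exon 26 (1 base in ex25): AGG, so the
  # exon-26-skipped variant reads A|GC.. = Ser as the first novel residue
  codons[830] <- "AGG"
  # frameshift terminators in exon 13: stops in both shifted frames, none in
  # frame 0 (CTA AGC covers +1, ACT AAC covers +2)
  codons[430:433] <- c("CTA", "AGC", "ACT", "AAC")

  # exon 27: "GC" completes the D26 junction codon; 48 nt encode the novel
  # tail residues 2..17; TAA stops the frameshifted frame; the reference
  # frame continues stop-free to its own TAA, then 3'UTR filler
  tail_codons <- .codons_for_tail(substr(D26_NOVEL_TAIL, 2, 17), prefix = "GC")
  ex27_core <- paste0("GC", tail_codons, "TAA", "C", "TAA")
  ex27_seq <- paste0(ex27_core,
                     substr(strrep("ACGGATCTTGCAGGTACTCA", 15), 1,
                            ex_len[["ex27"]] - nchar(ex27_core)))

  spliced <- paste0(utr, paste(codons, collapse = ""), ex27_seq)
  stopifnot(nchar(spliced) == total)

  # slice the spliced sequence back into exons
  starts <- cumsum(c(1, utils::head(ex_len, -1)))
  seqs <- substring(spliced, starts, starts + ex_len - 1)
  exon_df <- function(labels) {
    data.frame(label = labels, length = unname(ex_len[labels]),
               sequence = unname(seqs[match(labels, names(ex_len))]),
               stringsAsFactors = FALSE)
  }

  all_ex <- names(ex_len)
  tx201 <- transcript("201", exon_df(all_ex), "A", cds_start, TRUE)

  # 204: full-length twin with a shorter terminal exon (different 3'UTR end)
  df204 <- exon_df(all_ex)
  i27 <- match("ex27", df204$label)
  df204$length[i27] <- 250
  df204$sequence[i27] <- substr(df204$sequence[i27], 1, 250)
  tx204 <- transcript("204", df204, "A", cds_start, TRUE)

  # 205: truncated SH2-only, non-coding
  tx205 <- transcript("205", exon_df(paste0("ex", 1:5)), "A", NA, FALSE)

  # 202: exon-11 start (TSS-B); translation picks up the reference frame at
  # exon 11 base 2, so its protein is the reference's carboxyl portion
  tx202 <- transcript("202", exon_df(paste0("ex", 11:27)), "B", 2, TRUE)

  # 213: intron-14 start (TSS-C), non-coding; first unit is intron-14 derived
  in14_df <- data.frame(label = "in14", length = 80,
                        sequence = substr(strrep("GATTACACGTTGCAGT", 5), 1, 80),
                        stringsAsFactors = FALSE)
  tx213 <- transcript("213", rbind(in14_df, exon_df(paste0("ex", 15:27))),
                      "C", NA, FALSE)

  structure(list(
    transcripts = list(`201` = tx201, `204` = tx204, `205` = tx205,
                       `202` = tx202, `213` = tx213),
    domains = list(sh2 = c("ex2", "ex8"), phosphatase = c("ex15", "ex19")),
    primer_pairs = list(
      ex2_ex3 = c("ex2", "ex3"), ex10_ex12 = c("ex10", "ex12"),
      ex11_ex12 = c("ex11", "ex12"), ex15_ex16 = c("ex15", "ex16"),
      in14_ex16 = c("in14", "ex16")),
    annotations = list(d26_novel_tail = D26_NOVEL_TAIL,
                       d47 = list(exon = "ex12", offset = 0, length = 47),
                       d26 = list(exon = "ex26", offset = 0, length = 92)),
    tss = list(A = "ex1", B = "ex11", C = "in14")
  ), class = "isoform_catalog")
}

#' Derived D47 variant of a catalog transcript
#'
#' Deletes the first 47 nt of exon 12 (a frameshifting deletion introducing a
#' premature termination codon).
#'
#' @param catalog An `isoform_catalog`.
#' @param isoform Base isoform id (default the full-length reference "201").
#' @return Derived `transcript` with id `"<isoform>-D47"`.
#' @export
d47_variant <- function(catalog, isoform = "201") {
  d <- catalog$annotations$d47
  apply_deletion(catalog$transcripts[[isoform]], d$exon, d$offset, d$length,
                 variant_id = paste0(isoform, "-D47"))
}

#' Derived D26 (exon-26-skipped) variant of a catalog transcript
#'
#' Skips exon 26 entirely, frameshifting the terminal exon into a novel
#' carboxyl tail.
#'
#' @inheritParams d47_variant
#' @return Derived `transcript` with id `"<isoform>-D26"`.
#' @export
d26_variant <- function(catalog, isoform = "201") {
  d <- catalog$annotations$d26
  apply_deletion(catalog$transcripts[[isoform]], d$exon, d$offset, d$length,
                 variant_id = paste0(isoform, "-D26"))
}

#' Capture table: captured isoforms for every catalog primer pair
#'
#' @param catalog An `isoform_catalog`.
#' @return Named list mapping primer-pair name to the character vector of
#'   captured isoform ids (sorted).
#' @export
capture_table <- function(catalog) {
  lapply(catalog$primer_pairs, function(p) sort(capture_set(p, catalog)))
}

#' Isoforms assigned to a transcription start site
#'
#' @param catalog An `isoform_catalog`.
#' @param tss_label `"A"`, `"B"` or `"C"`.
#' @return Character vector of isoform ids whose TSS label matches.
#' @export
tss_isoforms <- function(catalog, tss_label) {
  ids <- names(catalog$transcripts)
  ids[vapply(catalog$transcripts, function(tx) tx$tss_label == tss_label,
             logical(1))]
}

CATALOG_SCHEMA_VERSION <- 1L

#' Write an isoform catalog to JSON
#'
#' Stable key order and a schema-version stamp; round-trips through
#' [read_catalog()].
#'
#' @param catalog An `isoform_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  obj <- list(
    schema_version = CATALOG_SCHEMA_VERSION,
    transcripts = lapply(catalog$transcripts, function(tx) {
      tl <- list(isoform_id = tx$isoform_id,
                 tss = tx$tss_label,
                 coding = tx$coding,
                 exons = lapply(seq_len(nrow(tx$exons)), function(i) {
                   e <- as.list(tx$exons[i, ])
                   if (is.null(e$sequence) || is.na(e$sequence)) e$sequence <- NULL
                   e
                 }))
      if (!is.na(tx$cds_start)) tl$cds_start <- tx$cds_start
      tl
    }),
    domains = catalog$domains,
    primer_pairs = catalog$primer_pairs,
    annotations = catalog$annotations,
    tss = catalog$tss
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an isoform catalog from JSON
#'
#' @param path Catalog JSON path (schema as written by [write_catalog()]).
#' @return An `isoform_catalog`.
#' @export
read_catalog <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- obj$schema_version %||% NA
  abort_if(!identical(as.integer(ver), CATALOG_SCHEMA_VERSION),
           "catalog schema version mismatch: file has %s, this package reads %d (no migration available)",
           as.character(ver), CATALOG_SCHEMA_VERSION)
  txs <- lapply(obj$transcripts, function(t) {
    exdf <- do.call(rbind, lapply(t$exons, function(e) {
      data.frame(label = e$label, length = as.numeric(e$length),
                 sequence = e$sequence %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
    cs <- t$cds_start
    if (is.null(cs) || length(cs) == 0) cs <- NA_real_
    transcript(t$isoform_id, exdf, t$tss, cds_start = as.numeric(cs),
               coding = isTRUE(t$coding))
  })
  names(txs) <- vapply(txs, `[[`, character(1), "isoform_id")
  structure(list(transcripts = txs,
                 domains = lapply(obj$domains, unlist),
                 primer_pairs = lapply(obj$primer_pairs, unlist),
                 annotations = obj$annotations,
                 tss = obj$tss),
            class = "isoform_catalog")
}
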