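# Transcript-isoform model: exon structures, primer capture sets, deletion
# variants, ORF / premature-termination-codon annotation, NMD candidacy and
# amplicon-length prediction.
#
# Coordinates are 1-based, closed, in spliced-transcript space. Exon labels
# follow the full-length reference transcript's global numbering ("ex1" ..
# "ex27"), with intron-derived first exons labelled "inN" (e.g. "in14" for the
# isoform whose transcription starts inside intron 14).

#' Global unit ordering for the packaged catalog topology
#' @return Character vector of exon/intron-unit labels in genomic order.
#' @export
catalog_unit_order <- function() {
  c(paste0("ex", 1:14), "in14", paste0("ex", 15:27))
}

#' Construct a transcript
#'
#' @param isoform_id Identifier, e.g. `"201"` or a derived id like `"201-D47"`.
#' @param exons data.frame with `label`, `length` (> 0) and optional
#'   `sequence` columns; labels must be unique and strictly ordered by the
#'   catalog's global unit order.
#' @param tss_label `"A"`, `"B"` or `"C"`.
#' @param cds_start 1-based position of the CDS start in spliced coordinates,
#'   or NA for non-coding transcripts.
#' @param coding Logical.
#' @return Object of class `transcript`.
#' @export
transcript <- function(isoform_id, exons, tss_label, cds_start = NA_real_,
                       coding = !is.na(cds_start)) {
  abort_if(any(exons$length <= 0), "exon lengths must be positive")
  ord <- match(exons$label, catalog_unit_order())
  abort_if(anyNA(ord), "unknown exon labels: %s",
           paste(exons$label[is.na(ord)], collapse = ", "))
  abort_if(is.unsorted(ord, strictly = TRUE),
           "exon labels must be strictly ordered by the global numbering")
  total <- sum(exons$length)
  abort_if(!is.na(cds_start) && (cds_start < 1 || cds_start > total),
           "cds_start %g outside the spliced transcript (length %d)",
           cds_start, total)
  if (!is.null(exons$sequence)) {
    has <- !is.na(exons$sequence)
    abort_if(any(nchar(exons$sequence[has]) != exons$length[has]),
             "exon sequence lengths disagree with declared lengths")
  }
  structure(list(isoform_id = isoform_id, exons = exons,
                 tss_label = tss_label, cds_start = cds_start,
                 coding = coding, deletions = list()),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("Transcript %s (TSS-%s, %s): %d exons, %d nt spliced%s\n",
              x$isoform_id, x$tss_label,
              if (x$coding) "coding" else "non-coding",
              nrow(x$exons), spliced_length(x),
              if (length(x$deletions)) sprintf(", %d deletion(s)",
                                               length(x$deletions)) else ""))
  invisible(x)
}

#' Spliced length of a transcript
#' @param tx A `transcript`.
#' @return Integer total length.
#' @export
spliced_length <- function(tx) sum(tx$exons$length)

#' Spliced nucleotide sequence of a transcript
#' @param tx A `transcript` whose exons carry sequences.
#' @return Single character string.
#' @export
spliced_sequence <- function(tx) {
  abort_if(is.null(tx$exons$sequence) || anyNA(tx$exons$sequence),
           "transcript %s has no full sequence", tx$isoform_id)
  paste(tx$exons$sequence, collapse = "")
}

# spliced start coordinate of each exon
exon_starts <- function(tx) {
  stats::setNames(cumsum(c(1, utils::head(tx$exons$length, -1))), tx$exons$label)
}

#' Isoforms captured by a primer pair
#'
#' A primer pair anchored in two exon/intron units captures exactly the
#' isoforms that contain both anchor units with no intervening exon of the
#' global numbering absent (a skipped exon between the anchors breaks the
#' contiguous template the pair was designed against; intron-derived units
#' between anchors are spliced out of most isoforms and do not count).
#'
#' @param primer_pair Character vector of two anchor labels,
#'   e.g. `c("ex10", "ex12")`.
#' @param catalog An `isoform_catalog`.
#' @return Character vector of captured isoform ids.
#' @export
capture_set <- function(primer_pair, catalog) {
  abort_if(length(primer_pair) != 2, "primer_pair must name two anchors")
  ord <- catalog_unit_order()
  idx <- match(primer_pair, ord)
  abort_if(anyNA(idx), "unknown anchor(s): %s",
           paste(primer_pair[is.na(idx)], collapse = ", "))
  rng <- range(idx)
  between <- ord[seq(rng[1], rng[2])]
  between_exons <- setdiff(grep("^ex", between, value = TRUE), primer_pair)
  captured <- vapply(catalog$transcripts, function(tx) {
    labs <- tx$exons$label
    all(primer_pair %in% labs) && all(between_exons %in% labs)
  }, logical(1))
  names(catalog$transcripts)[captured]
}

#' Apply a deletion to a transcript, producing a derived variant
#'
#' Removes `length_nt` bases starting `offset_nt` bases into the named exon
#' (offset 0 = the exon's first base); a whole-exon skip is offset 0 with the
#' full exon length. The spliced length shrinks by exactly `length_nt` and
#' the deletion is recorded (in original-exon coordinates) on the variant.
#'
#' @param tx A `transcript`.
#' @param exon_label Exon to delete from.
#' @param offset_nt 0-based offset into the exon.
#' @param length_nt Bases to delete (`offset_nt + length_nt` must not exceed
#'   the exon length); 0 returns the transcript unchanged.
#' @param variant_id Id for the derived transcript (default
#'   `"<id>-d<length>"` style).
#' @return The derived `transcript`.
#' @export
apply_deletion <- function(tx, exon_label, offset_nt, length_nt,
                           variant_id = NULL) {
  i <- match(exon_label, tx$exons$label)
  abort_if(is.na(i), "transcript %s has no exon %s", tx$isoform_id, exon_label)
  abort_if(any(vapply(tx$deletions, function(d) d$exon_label == exon_label,
                      logical(1))),
           "exon %s already carries a deletion", exon_label)
  L <- tx$exons$length[i]
  abort_if(offset_nt < 0 || length_nt < 0 || offset_nt + length_nt > L,
           "deletion %d+%d exceeds exon %s boundary (length %d)",
           offset_nt, length_nt, exon_label, L)
  if (length_nt == 0) return(tx)

  del_start_spliced <- exon_starts(tx)[[exon_label]] + offset_nt
  out <- tx
  if (length_nt == L) {
    out$exons <- tx$exons[-i, , drop = FALSE]
  } else {
    out$exons$length[i] <- L - length_nt
    if (!is.null(tx$exons$sequence) && !is.na(tx$exons$sequence[i])) {
      s <- tx$exons$sequence[i]
      out$exons$sequence[i] <- paste0(substr(s, 1, offset_nt),
                                      substr(s, offset_nt + length_nt + 1, L))
    }
  }
  rownames(out$exons) <- NULL
  if (!is.na(tx$cds_start)) {
    abort_if(del_start_spliced < tx$cds_start &&
               del_start_spliced + length_nt - 1 >= tx$cds_start,
             "deletion overlaps the CDS start")
    if (del_start_spliced + length_nt - 1 < tx$cds_start)
      out$cds_start <- tx$cds_start - length_nt
  }
  out$deletions <- c(tx$deletions,
                     list(list(exon_label = exon_label, offset_nt = offset_nt,
                               length_nt = length_nt, skip = length_nt == L)))
  out$isoform_id <- variant_id %||%
    sprintf("%s-d%s_%d", tx$isoform_id, exon_label, length_nt)
  out
}

# translate a CDS string up to (not including) the first stop; returns
# list(protein, has_stop, n_codons_to_stop)
.translate_cds <- function(cds) {
  n <- floor(nchar(cds) / 3) * 3
  abort_if(n < 3, "CDS shorter than one codon")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, n)),
    if.fuzzy.codon = "solve"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    list(protein = substr(aa, 1, stop_at - 1), has_stop = TRUE,
         stop_codon = as.integer(stop_at))
  } else {
    list(protein = aa, has_stop = FALSE, stop_codon = NA_integer_)
  }
}

#' Annotate the open reading frame of a (possibly deletion-bearing) transcript
#'
#' Translates from the transcript's CDS start to the first stop codon and
#' compares the protein with the reference transcript's. A simple deletion
#' causes a frameshift exactly when its length is not a multiple of 3; in a
#' frameshifted transcript the residues after the last reference-matching
#' position form the novel carboxyl tail, and a stop arising before the
#' reference protein's end is flagged as a premature termination codon (PTC).
#' Transcripts with no in-frame stop before the transcript end are flagged
#' `non_stop` rather than failing.
#'
#' @param tx A coding `transcript` carrying sequence and `cds_start`.
#' @param reference The reference `transcript` (defaults to `tx`, in which
#'   case the annotation is purely the translation).
#' @return Object of class `orf_annotation`: `protein`, `frameshift`,
#'   `ptc_position` (1-based codon index of the premature stop, NA if none),
#'   `ptc_nt_end` (spliced coordinate of the stop codon's last base),
#'   `novel_tail`, `non_stop`, `deletions`.
#' @export
annotate_orf <- function(tx, reference = tx) {
  abort_if(!isTRUE(tx$coding) || is.na(tx$cds_start),
           "transcript %s is not coding / has no CDS start", tx$isoform_id)
  cds <- substr(spliced_sequence(tx), tx$cds_start, spliced_length(tx))
  tr <- .translate_cds(cds)

  ref_protein <- if (identical(reference$isoform_id, tx$isoform_id) &&
                     length(tx$deletions) == 0) {
    tr$protein
  } else {
    ref_cds <- substr(spliced_sequence(reference), reference$cds_start,
                      spliced_length(reference))
    .translate_cds(ref_cds)$protein
  }

  cds_del <- sum(vapply(tx$deletions, `[[`, numeric(1), "length_nt"))
  frameshift <- length(tx$deletions) > 0 && (cds_del %% 3) != 0

  # longest common prefix with the reference protein
  pmin_len <- min(nchar(tr$protein), nchar(ref_protein))
  lcp <- 0
  if (pmin_len > 0) {
    a <- utf8ToInt(substr(tr$protein, 1, pmin_len))
    b <- utf8ToInt(substr(ref_protein, 1, pmin_len))
    d <- which(a != b)
    lcp <- if (length(d)) d[1] - 1L else pmin_len
  }
  novel_tail <- if (frameshift) substr(tr$protein, lcp + 1, nchar(tr$protein)) else ""

  # a stop is premature when a deletion-derived variant terminates before its
  # reference does; natural isoforms that merely start downstream are not
  # PTC-bearing
  premature <- length(tx$deletions) > 0 && tr$has_stop &&
    nchar(tr$protein) < nchar(ref_protein)
  ptc <- if (premature) tr$stop_codon else NA_integer_
  ptc_nt_end <- if (premature) tx$cds_start + ptc * 3 - 1 else NA_real_

  structure(list(protein = tr$protein, frameshift = frameshift,
                 ptc_position = ptc, ptc_nt_end = ptc_nt_end,
                 novel_tail = novel_tail, non_stop = !tr$has_stop,
                 deletions = tx$deletions),
            class = "orf_annotation")
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat(sprintf("ORF: %d aa%s%s%s\n", nchar(x$protein),
              if (x$frameshift) ", frameshifted" else "",
              if (!is.na(x$ptc_position)) sprintf(", PTC at codon %d", x$ptc_position) else "",
              if (nzchar(x$novel_tail)) sprintf(", novel tail %s", x$novel_tail) else ""))
  invisible(x)
}

#' Is a PTC-bearing transcript a nonsense-mediated-decay candidate?
#'
#' Applies the classic junction rule: a premature stop codon triggers NMD
#' when it lies more than `rule_threshold_nt` (default 50) upstream of the
#' final exon-exon junction. The comparison is strict — a PTC exactly at the
#' threshold is not a candidate — and a PTC within the last exon, or any stop
#' in a single-exon transcript, never is.
#'
#' @param tx The `transcript` the PTC lives on.
#' @param ptc_position 1-based codon index of the stop (as from
#'   [annotate_orf()]).
#' @param rule_threshold_nt Junction-distance threshold in nt (default 50).
#' @return Logical.
#' @export
nmd_candidate <- function(tx, ptc_position, rule_threshold_nt = 50) {
  abort_if(is.na(ptc_position) || ptc_position < 1, "invalid PTC position")
  if (nrow(tx$exons) < 2) return(FALSE)
  ptc_nt_end <- tx$cds_start + ptc_position * 3 - 1
  last_junction <- spliced_length(tx) - tx$exons$length[nrow(tx$exons)]
  (last_junction - ptc_nt_end) > rule_threshold_nt
}

# map a 1-based offset within an exon's ORIGINAL coordinates onto the
# (possibly deletion-bearing) transcript; NA if the base is deleted
.map_exon_offset <- function(tx, exon_label, offset) {
  dels <- Filter(function(d) d$exon_label == exon_label, tx$deletions)
  shift <- 0
  for (d in dels) {
    if (offset > d$offset_nt && offset <= d$offset_nt + d$length_nt)
      return(NA_real_)                       # anchor base itself deleted
    if (offset > d$offset_nt + d$length_nt) shift <- shift + d$length_nt
  }
  offset - shift
}

#' Predict the amplicon length of a primer pair on a transcript
#'
#' Primer anchor positions are given in the coordinate system of the
#' reference isoform's exons (1-based offsets within the named exons); the
#' product is measured on the supplied transcript, so a deletion variant
#' yields a product shortened by the deleted overlap and a transcript missing
#' either primer's exon (or the anchor base itself) yields no product.
#'
#' @param primer_pair List with `fwd` and `rev`, each `list(exon =, offset =)`;
#'   `fwd$offset` is the product's first base, `rev$offset` its last base,
#'   within the respective (original) exon.
#' @param tx Target `transcript`.
#' @return Product length in nt, or `NA` for no product.
#' @export
predict_amplicon_length <- function(primer_pair, tx) {
  anchors <- list(primer_pair$fwd, primer_pair$rev)
  pos <- numeric(2)
  orig_len <- function(lab) {
    i <- match(lab, tx$exons$label)
    L <- if (is.na(i)) NA else tx$exons$length[i]
    for (d in tx$deletions) if (d$exon_label == lab) L <- L + d$length_nt
    L
  }
  for (j in 1:2) {
    a <- anchors[[j]]
    skipped <- any(vapply(tx$deletions,
                          function(d) d$skip && d$exon_label == a$exon,
                          logical(1)))
    if (skipped || !a$exon %in% tx$exons$label) return(NA_real_)
    L0 <- orig_len(a$exon)
    abort_if(a$offset < 1 || a$offset > L0,
             "primer offset %d outside exon %s (length %d)", a$offset, a$exon, L0)
    mapped <- .map_exon_offset(tx, a$exon, a$offset)
    if (is.na(mapped)) return(NA_real_)
    pos[j] <- exon_starts(tx)[[a$exon]] + mapped - 1
  }
  abort_if(pos[2] < pos[1], "reverse primer lies upstream of forward primer")
  pos[2] - pos[1] + 1
}
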