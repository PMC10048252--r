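# Isoform catalog: capture sets, deletion variants, ORF/PTC/NMD annotation
# and amplicon-length prediction.

catalog <- toy_catalog()

test_that("capture table matches the isoform-assay legend for all five pairs", {
  tab <- capture_table(catalog)
  expect_equal(tab$ex2_ex3, c("201", "204", "205"))
  expect_equal(tab$ex10_ex12, c("201", "204"))
  expect_equal(tab$ex11_ex12, c("201", "202", "204"))
  expect_equal(tab$ex15_ex16, c("201", "202", "204", "213"))
  expect_equal(tab$in14_ex16, "213")
  expect_error(capture_set(c("ex99", "ex100"), catalog), "unknown anchor")
})

test_that("TSS assignments map to the expected isoform sets", {
  expect_setequal(tss_isoforms(catalog, "A"), c("201", "204", "205"))
  expect_equal(tss_isoforms(catalog, "B"), "202")
  expect_equal(tss_isoforms(catalog, "C"), "213")
})

test_that("deletions keep exact length bookkeeping and validate bounds", {
  tx <- catalog$transcripts[["201"]]
  d47 <- apply_deletion(tx, "ex12", 0, 47)
  expect_equal(spliced_length(tx) - spliced_length(d47), 47)
  expect_identical(apply_deletion(tx, "ex12", 0, 0), tx)
  expect_error(apply_deletion(tx, "ex12", 180, 47), "exceeds")
  expect_error(apply_deletion(tx, "ex99", 0, 10), "no exon")
  # whole-exon skip removes the exon
  d26 <- apply_deletion(tx, "ex26", 0, 92)
  expect_false("ex26" %in% d26$exons$label)
  expect_equal(spliced_length(tx) - spliced_length(d26), 92)
})

test_that("ORF annotation translates correctly and flags frameshifts", {
  mini <- transcript("toy", data.frame(label = "ex1", length = 13,
                                       sequence = "AAAAATGAAATAG"),
                     "A", cds_start = 5, coding = TRUE)
  a <- annotate_orf(mini)
  expect_equal(a$protein, "MK")
  expect_false(a$frameshift)
  expect_equal(a$novel_tail, "")
  expect_true(is.na(a$ptc_position))

  # 1-nt deletion in codon 2 of a toy reference: shifted frame translated by
  # the independent codon-table oracle
  ref <- transcript("ref", data.frame(label = c("ex1", "ex2"),
                                      length = c(9, 12),
                                      sequence = c("ATGAAACCC", "GTAGTAACCTAA")),
                    "A", cds_start = 1, coding = TRUE)
  var <- apply_deletion(ref, "ex1", 3, 1)   # drops one base of codon 2
  av <- annotate_orf(var, ref)
  expect_true(av$frameshift)
  shifted_cds <- paste0("ATG", "AACCC", "GTAGTAACCTAA")
  expect_equal(av$protein, oracle_translate(shifted_cds))
  expect_equal(av$ptc_position, nchar(av$protein) + 1)
  expect_true(nzchar(av$novel_tail))

  # frameshift flag is exactly (deletion length mod 3 != 0)
  for (len in c(3, 6)) {
    v3 <- annotate_orf(apply_deletion(ref, "ex2", 0, len), ref)
    expect_false(v3$frameshift)
  }
})

test_that("translation agrees with a codon-table oracle on random CDSs", {
  set.seed(314)
  for (i in 1:100) {
    n_codons <- sample(5:40, 1)
    cds <- paste0("ATG", paste(sample(c("A", "C", "G", "T"),
                                      3 * n_codons, TRUE), collapse = ""),
                  "TAA")
    tx <- transcript("r", data.frame(label = "ex1", length = nchar(cds),
                                     sequence = cds), "A", 1, TRUE)
    expect_equal(annotate_orf(tx)$protein, oracle_translate(cds))
  }
})

test_that("the packaged D47 variant frameshifts into an NMD-candidate PTC", {
  ref <- catalog$transcripts[["201"]]
  d47 <- d47_variant(catalog)
  a <- annotate_orf(d47, ref)
  expect_true(a$frameshift)   # 47 mod 3 != 0
  expect_false(is.na(a$ptc_position))
  expect_true(nmd_candidate(d47, a$ptc_position))
  # protein keeps only the amino-terminal (SH2-side) portion
  expect_lt(nchar(a$protein), nchar(annotate_orf(ref)$protein) / 2)
})

test_that("the packaged D26 variant ends in the annotated 17-residue tail", {
  ref <- catalog$transcripts[["201"]]
  d26 <- d26_variant(catalog)
  a <- annotate_orf(d26, ref)
  expect_true(a$frameshift)
  expect_equal(a$novel_tail, "SEALSELPLSREPRGTA")
  expect_equal(nchar(a$novel_tail), 17)
  expect_equal(a$novel_tail, catalog$annotations$d26_novel_tail)
  # its stop lies in the last exon: stable mRNA, not an NMD candidate
  expect_false(nmd_candidate(d26, a$ptc_position))
})

test_that("NMD junction rule applies the strict 50-nt threshold", {
  mk <- function(cds_start, len1, len2) transcript(
    "t", data.frame(label = c("ex1", "ex2"), length = c(len1, len2),
                    sequence = c(strrep("A", len1), strrep("A", len2))),
    "A", cds_start, TRUE)
  # PTC 200 nt upstream of the last junction
  tx <- mk(1, 400, 100)
  expect_true(nmd_candidate(tx, ptc_position = 67))   # ends nt 201, junction 400
  # PTC within the last exon
  expect_false(nmd_candidate(tx, ptc_position = 140)) # ends nt 420
  # exactly 50 nt upstream: strict inequality says no
  tx2 <- mk(3, 400, 100)
  expect_false(nmd_candidate(tx2, ptc_position = 116)) # ends nt 350, 50 from junction
  expect_true(nmd_candidate(tx2, ptc_position = 115))  # 53 nt upstream
  single <- transcript("s", data.frame(label = "ex1", length = 300,
                                       sequence = strrep("A", 300)), "A", 1, TRUE)
  expect_false(nmd_candidate(single, 10))
})

test_that("amplicon lengths shrink by the deleted overlap and vanish with the exon", {
  ref <- catalog$transcripts[["201"]]
  d47 <- d47_variant(catalog)
  pp <- list(fwd = list(exon = "ex9", offset = 43),
             rev = list(exon = "ex12", offset = 100))
  expect_equal(predict_amplicon_length(pp, ref), 458)
  expect_equal(predict_amplicon_length(pp, d47), 411)
  expect_equal(458 - 411, 47)
  # every toy deletion upstream of the reverse anchor: reference minus
  # variant equals the deleted overlap with the product
  for (del in list(c(0, 47), c(10, 30), c(50, 40))) {
    v <- apply_deletion(ref, "ex12", del[1], del[2])
    overlap <- max(0, min(99, del[1] + del[2]) - del[1])
    expect_equal(predict_amplicon_length(pp, ref) -
                   predict_amplicon_length(pp, v), overlap)
  }
  # pair fully inside one exon: length = primer span
  pp_in <- list(fwd = list(exon = "ex12", offset = 60),
                rev = list(exon = "ex12", offset = 130))
  expect_equal(predict_amplicon_length(pp_in, ref), 71)
  # anchor exon skipped: no product
  d26 <- d26_variant(catalog)
  pp26 <- list(fwd = list(exon = "ex26", offset = 5),
               rev = list(exon = "ex26", offset = 60))
  expect_true(is.na(predict_amplicon_length(pp26, d26)))
  # anchor base itself deleted: no product
  pp_del <- list(fwd = list(exon = "ex12", offset = 20),
                 rev = list(exon = "ex12", offset = 130))
  expect_true(is.na(predict_amplicon_length(pp_del, d47)))
  expect_error(predict_amplicon_length(
    list(fwd = list(exon = "ex12", offset = 500),
         rev = list(exon = "ex12", offset = 510)), ref), "outside")
})

test_that("catalog round-trips through JSON byte-stably", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_catalog(catalog, f1)
  back <- read_catalog(f1)
  expect_equal(names(back$transcripts), names(catalog$transcripts))
  expect_equal(capture_table(back), capture_table(catalog))
  expect_equal(spliced_sequence(back$transcripts[["201"]]),
               spliced_sequence(catalog$transcripts[["201"]]))
  write_catalog(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # schema guard
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = 99), bad, auto_unbox = TRUE)
  expect_error(read_catalog(bad), "schema version mismatch")
})
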