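# File formats: sample sheets, metadata-stamped TSV tables, JSON results.
#
# Tabular outputs are TSV with a header line preceded by "#"-prefixed
# metadata lines (schema name/version first); nested results are JSON.

TSV_SCHEMAS <- c(allele_counts = 1L, aei_records = 1L)

#' Read and validate a sample sheet
#'
#' CSV with one row per sample (or per sample x material for sequencing
#' sheets). Required columns: `sample_id`, the three `genotype_*` columns,
#' `niari`, `ad_status`. Optional: `barcode`, `material`, `sex`, `age_years`,
#' `pmi_hours`. Genotype strings are allele-order-insensitive ("CT" and "TC"
#' are the same heterozygote) and are normalized to the package's canonical
#' minor-first form; illegal genotype codes are reported with their row
#' numbers.
#'
#' @param path CSV path.
#' @return Validated data.frame with normalized genotype columns.
#' @export
read_sample_sheet <- function(path) {
  abort_if(!file.exists(path), "sample sheet not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "genotype_rs35349669", "genotype_rs10933431",
                "genotype_rs1141328", "niari", "ad_status")
  miss <- setdiff(required, names(df))
  abort_if(length(miss) > 0, "sample sheet missing column(s): %s",
           paste(miss, collapse = ", "))

  for (snp in names(snp_alleles)) {
    col <- paste0("genotype_", snp)
    al <- unname(snp_alleles[[snp]])
    g <- df[[col]]
    chars <- strsplit(toupper(g), "")
    ok <- !is.na(g) & nchar(g) == 2 &
      vapply(chars, function(x) all(x %in% al), logical(1))
    abort_if(any(!ok), "illegal %s genotype code(s) in row(s): %s", snp,
             paste(which(!ok), collapse = ", "))
    df[[col]] <- vapply(chars, function(x)
      canon_genotype(x[1], x[2], snp), character(1))
  }
  bad_niari <- !df$niari %in% c("low", "high")
  abort_if(any(bad_niari), "illegal niari value(s) in row(s): %s",
           paste(which(bad_niari), collapse = ", "))
  df
}

# generic TSV-with-metadata writer/reader ---------------------------------

write_tsv_with_meta <- function(df, path, schema, meta = character(0)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#schema=%s/%d", schema, TSV_SCHEMAS[[schema]]),
               paste0("#", meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_with_meta <- function(path, schema) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  abort_if(length(meta) == 0 ||
             !identical(meta[1], sprintf("#schema=%s/%d", schema,
                                         TSV_SCHEMAS[[schema]])),
           "schema mismatch reading %s: expected %s/%d, file says '%s' (no migration available)",
           path, schema, TSV_SCHEMAS[[schema]],
           if (length(meta)) sub("^#schema=", "", meta[1]) else "<none>")
  body <- which(!grepl("^#", lines))
  header <- strsplit(lines[body[1]], "\t")[[1]]
  rows <- body[-1]
  fields <- strsplit(lines[rows], "\t")
  bad <- which(lengths(fields) != length(header))
  abort_if(length(bad) > 0, "corrupted row(s) in %s at line(s): %s",
           path, paste(rows[bad], collapse = ", "))
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Write / read an allele-counts table
#'
#' One row per sample x material with the four count categories; count
#' conservation is re-validated on read-back.
#'
#' @param counts data.frame of stacked [count_alleles()] rows.
#' @param path TSV path.
#' @return `path` (write) / validated data.frame (read).
#' @export
write_allele_counts <- function(counts, path) {
  write_tsv_with_meta(
    counts[c("sample_id", "material", "n_allele1", "n_allele2",
             "n_ambiguous", "n_unassigned", "n_total")],
    path, "allele_counts")
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  df <- read_tsv_with_meta(path, "allele_counts")
  num <- c("n_allele1", "n_allele2", "n_ambiguous", "n_unassigned", "n_total")
  df[num] <- lapply(df[num], as.integer)
  bad <- with(df, n_allele1 + n_allele2 + n_ambiguous + n_unassigned != n_total)
  abort_if(any(bad), "count conservation violated in %s for sample(s): %s",
           path, paste(df$sample_id[bad], collapse = ", "))
  class(df) <- c("allele_counts", class(df))
  df
}

#' Write / read an AEI record table
#'
#' @param records [aei_records()] table.
#' @param path TSV path.
#' @return `path` (write) / data.frame (read).
#' @export
write_aei_records <- function(records, path) {
  write_tsv_with_meta(records, path, "aei_records")
}

#' @rdname write_aei_records
#' @export
read_aei_records <- function(path) {
  df <- read_tsv_with_meta(path, "aei_records")
  num <- c("raw_ratio_cdna", "raw_ratio_gdna", "normalized_ratio",
           "aei_magnitude")
  df[num] <- lapply(df[num], as.numeric)
  df$included <- as.logical(df$included)
  class(df) <- c("aei_records", class(df))
  df
}

#' Write a nested result (model fit, test result, run report) as JSON
#'
#' @param x A list-like result object.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_json_result <- function(x, path) {
  if (inherits(x, "expression_model_fit")) x$fit <- NULL
  x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Read a JSON result written by [write_json_result()]
#' @param path JSON path.
#' @return List.
#' @export
read_json_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Generate a set of mutually distinguishable sample barcodes
#'
#' Deterministic 8-nt barcodes built from doubled base-4 digits, so any two
#' barcodes differ in at least two positions.
#'
#' @param n Number of barcodes (<= 256).
#' @return Character vector of length `n`.
#' @export
make_barcodes <- function(n) {
  abort_if(n > 256, "at most 256 barcodes available")
  idx <- seq_len(n) - 1L
  digits <- cbind(idx %/% 64, (idx %/% 16) %% 4, (idx %/% 4) %% 4, idx %% 4)
  apply(digits, 1, function(d)
    paste(strrep(DNA_BASES[d + 1L], 2), collapse = ""))
}
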