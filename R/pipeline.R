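# Pipeline driver: simulate -> count -> AEI and qPCR -> models, with a
# machine-readable run manifest. All randomness derives from one seed via
# stage-named substreams (see derive_seed), so each stage is independently
# reproducible and the full run is checksum-stable.

#' Run the simulation-to-analysis pipeline
#'
#' Executes the requested stages into `out_dir`:
#' \describe{
#'   \item{simulate}{cohort + expression states; writes `sample_sheet.csv`,
#'     per-run `sim_config.json` sidecar, and a multiplexed `reads.fastq`
#'     (cDNA and gDNA amplicons for every reporter heterozygote).}
#'   \item{count}{demultiplexes the FASTQ and counts reporter alleles;
#'     writes `allele_counts.tsv` and `count_report.json`.}
#'   \item{aei}{gDNA-normalized AEI records and both conditional
#'     genotype-stratified tests; writes `aei_records.tsv` and
#'     `aei_tests.json`.}
#'   \item{qpcr}{simulated plate, standard-curve quantitation and
#'     NIARI/genotype expression models per assay; writes
#'     `qpcr_model_fits.json`.}
#' }
#' A `manifest.json` (config, package version, output checksums) is written
#' at the end. On a stage error, files already written are renamed with a
#' `.partial` suffix and the error is re-thrown with the stage name.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param config A [sim_config()]; its `seed` is overridden by `seed`.
#' @param cohort_n Cohort size for the simulate stage.
#' @param stages Character subset of `c("simulate", "count", "aei", "qpcr")`.
#' @param kmer_spec Reporter-SNP bracket spec.
#' @param test_snp,conditioning_snp SNPs for the primary conditional test
#'   (the reciprocal test is run too).
#' @param norm_mode gDNA normalization mode.
#' @param min_depth AEI depth filter.
#' @return Invisible list of stage results (cohort, counts, aei, qpcr,
#'   manifest path).
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = sim_config(),
                         cohort_n = 56,
                         stages = c("simulate", "count", "aei", "qpcr"),
                         kmer_spec = "GCCGGCCC[G/A]GCCGAGG",
                         test_snp = "rs35349669",
                         conditioning_snp = "rs10933431",
                         norm_mode = "cohort_mean", min_depth = 100L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }
  current_stage <- "setup"
  result <- list()

  run <- function() {
    kmer <- parse_allele_kmer(kmer_spec)

    if ("simulate" %in% stages) {
      current_stage <<- "simulate"
      hap <- haplotype_frequencies(0.498, 0.220, 0.18)
      cohort <- simulate_cohort(cohort_n, hap, seed = derive_seed(seed, "cohort"))
      expr <- simulate_expression(cohort, config,
                                  seed = derive_seed(seed, "expression"))
      het <- cohort[is_het(cohort$genotype_rs1141328), , drop = FALSE]
      bc <- make_barcodes(2 * nrow(het))
      sheet <- do.call(rbind, lapply(c("cDNA", "gDNA"), function(mat) {
        s <- cohort[cohort$sample_id %in% het$sample_id,
                    setdiff(names(cohort), grep("^hap", names(cohort), value = TRUE))]
        s$material <- mat
        s
      }))
      sheet$barcode <- bc
      utils::write.csv(sheet, note(file.path(out_dir, "sample_sheet.csv")),
                       row.names = FALSE)
      cfg <- unclass(config); cfg$seed <- seed
      jsonlite::write_json(cfg, note(file.path(out_dir, "sim_config.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)

      reads <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
        row <- sheet[i, ]
        es <- expr[expr$sample_id == row$sample_id, , drop = FALSE]
        simulate_amplicon_reads(
          row, row$material, es, kmer, depth = config$depth,
          error_rate = config$error_rate, barcode = row$barcode,
          seed = derive_seed(seed, paste0("reads_", row$sample_id, "_",
                                          row$material)))
      }))
      write_fastq(reads, note(file.path(out_dir, "reads.fastq")))
      result$cohort <<- cohort
      result$expression <<- expr
    }

    if ("count" %in% stages) {
      current_stage <<- "count"
      fq <- file.path(out_dir, "reads.fastq")
      abort_if(!file.exists(fq), "input FASTQ not found: %s", fq)
      sheet <- utils::read.csv(file.path(out_dir, "sample_sheet.csv"),
                               stringsAsFactors = FALSE)
      reads <- read_fastq(fq)
      bmap <- stats::setNames(sheet$barcode,
                              paste(sheet$sample_id, sheet$material, sep = "|"))
      buckets <- demultiplex(reads, bmap)
      counts <- do.call(rbind, lapply(names(bmap), function(key) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        count_alleles(buckets[[key]], kmer, sample_id = parts[1],
                      material = parts[2])
      }))
      write_allele_counts(counts, note(file.path(out_dir, "allele_counts.tsv")))
      write_json_result(
        list(kmer_spec = kmer_spec, allow_revcomp = TRUE, max_mismatch = 0,
             n_reads = nrow(reads), n_unassigned_barcode = nrow(buckets$unassigned),
             totals = colSums(counts[c("n_allele1", "n_allele2", "n_ambiguous",
                                       "n_unassigned")])),
        note(file.path(out_dir, "count_report.json")))
      result$counts <<- counts
    }

    if ("aei" %in% stages) {
      current_stage <<- "aei"
      counts <- read_allele_counts(file.path(out_dir, "allele_counts.tsv"))
      sheet <- utils::read.csv(file.path(out_dir, "sample_sheet.csv"),
                               stringsAsFactors = FALSE)
      sheet <- sheet[!duplicated(sheet$sample_id), ]
      rec <- aei_records(counts, min_depth = min_depth, mode = norm_mode)
      write_aei_records(rec, note(file.path(out_dir, "aei_records.tsv")))
      t1 <- conditional_aei_test(rec, sheet, test_snp, conditioning_snp)
      t2 <- conditional_aei_test(rec, sheet, conditioning_snp, test_snp)
      write_json_result(
        list(primary = list(test_snp = test_snp,
                            conditioning_snp = conditioning_snp,
                            n_homozygous = length(t1$strata$group_homozygous),
                            n_heterozygous = length(t1$strata$group_heterozygous),
                            u = t1$test$u_statistic, p = t1$test$p_two_sided,
                            method = t1$test$method),
             reciprocal = list(test_snp = conditioning_snp,
                               conditioning_snp = test_snp,
                               u = t2$test$u_statistic, p = t2$test$p_two_sided,
                               method = t2$test$method)),
        note(file.path(out_dir, "aei_tests.json")))
      result$aei <<- list(records = rec, primary = t1, reciprocal = t2)
    }

    if ("qpcr" %in% stages) {
      current_stage <<- "qpcr"
      abort_if(is.null(result$cohort),
               "qpcr stage requires the simulate stage in the same run")
      curve <- list(slope = -3.3219, intercept = 37)
      plate <- simulate_qpcr_plate(result$expression, curve,
                                   qpcr_sd = config$qpcr_sd,
                                   seed = derive_seed(seed, "qpcr"))
      quant <- quantitate_plate(plate)
      wide <- stats::reshape(quant$copies[c("sample", "assay", "copies")],
                             idvar = "sample", timevar = "assay",
                             direction = "wide")
      names(wide) <- sub("^copies\\.", "", names(wide))
      df <- merge(result$cohort, wide, by.x = "sample_id", by.y = "sample")
      df$niari_high <- as.numeric(df$niari == "high")
      df$dose_rs35349669 <- genotype_dose(df$genotype_rs35349669, "rs35349669")
      df$dose_rs10933431 <- genotype_dose(df$genotype_rs10933431, "rs10933431")
      df$log_itgam <- log10(df$itgam)
      fits <- lapply(setdiff(assay_names(), "itgam"), function(a) {
        df$log_target <- log10(df[[a]])
        fit <- fit_expression_model(df, "log_target",
                                    c("log_itgam", "niari_high",
                                      "dose_rs35349669", "dose_rs10933431"))
        list(assay = a, beta_std = as.list(fit$beta_std),
             p_values = as.list(fit$p_values),
             adj_r_squared = fit$adj_r_squared, n = fit$n)
      })
      write_json_result(fits, note(file.path(out_dir, "qpcr_model_fits.json")))
      result$qpcr <<- fits
    }

    current_stage <<- "manifest"
    manifest <- list(
      package = "ampliconAEI",
      version = as.character(utils::packageVersion("ampliconAEI")),
      seed = seed,
      stages = stages,
      config = unclass(config),
      checksums = as.list(tools::md5sum(sort(written)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <<- file.path(out_dir, "manifest.json")
  }

  tryCatch(run(), error = function(e) {
    for (f in written) if (file.exists(f))
      file.rename(f, paste0(f, ".partial"))
    stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
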