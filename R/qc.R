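#' Quality control of a genotype dataset
#'
#' Applies the standard chip-data filters in a fixed, configurable order:
#' keep autosomal SNPs, keep SNPs with call rate strictly above
#' `snp_call_rate_min`, keep samples with missingness strictly below
#' `sample_missing_max`. Boundary cases are strict on purpose: a SNP with a
#' call rate of exactly 0.95 and a sample with missingness of exactly 0.10
#' are both removed.
#'
#' @param ds a [geno_dataset].
#' @param snp_call_rate_min minimum SNP call rate, in (0, 1]; retained SNPs
#'   have call rate `>` this value.
#' @param sample_missing_max maximum per-sample missing fraction, in (0, 1];
#'   retained samples have missingness `<` this value.
#' @param autosomes chromosome labels treated as autosomes (goat default
#'   `"1"`..`"29"`).
#' @param filter_order permutation of `c("autosomes", "snp", "sample")`; the
#'   default computes SNP call rate before any sample is removed.
#' @return a list with `dataset` (the filtered [geno_dataset]) and `report`
#'   (a `qc_report`: counts removed at each step and retained totals).
#' @export
apply_qc <- function(ds,
                     snp_call_rate_min = 0.95,
                     sample_missing_max = 0.10,
                     autosomes = as.character(1:29),
                     filter_order = c("autosomes", "snp", "sample")) {
  stopifnot(snp_call_rate_min > 0, snp_call_rate_min <= 1,
            sample_missing_max > 0, sample_missing_max <= 1)
  if (!setequal(filter_order, c("autosomes", "snp", "sample"))) {
    stop("filter_order must be a permutation of autosomes, snp, sample")
  }
  removed <- c(snps_non_autosomal = 0L, snps_low_call_rate = 0L,
               samples_high_missing = 0L)
  for (step in filter_order) {
    if (step == "autosomes") {
      keep <- ds$map$chrom %in% autosomes
      removed["snps_non_autosomal"] <- sum(!keep)
      if (!any(keep)) stop("QC step 'autosomes' removed every SNP")
      ds <- subset_genotypes(ds, loci = keep)
    } else if (step == "snp") {
      call_rate <- 1 - colMeans(is.na(ds$calls))
      keep <- call_rate > snp_call_rate_min
      removed["snps_low_call_rate"] <- sum(!keep)
      if (!any(keep)) stop("QC step 'snp' (call rate) removed every SNP")
      ds <- subset_genotypes(ds, loci = keep)
    } else {
      missing <- rowMeans(is.na(ds$calls))
      keep <- missing < sample_missing_max
      removed["samples_high_missing"] <- sum(!keep)
      if (!any(keep)) stop("QC step 'sample' (missingness) removed every sample")
      ds <- subset_genotypes(ds, samples = keep)
    }
  }
  report <- structure(
    list(removed = as.list(removed),
         retained = list(samples = n_samples(ds), snps = n_loci(ds)),
         thresholds = list(snp_call_rate_min = snp_call_rate_min,
                           sample_missing_max = sample_missing_max),
         filter_order = filter_order),
    class = "qc_report")
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (order:", paste(x$filter_order, collapse = " -> "), ")\n")
  cat("  non-autosomal SNPs removed: ", x$removed$snps_non_autosomal, "\n")
  cat("  low call-rate SNPs removed: ", x$removed$snps_low_call_rate,
      sprintf(" (call rate > %g kept)\n", x$thresholds$snp_call_rate_min))
  cat("  high-missing samples removed:", x$removed$samples_high_missing,
      sprintf(" (missingness < %g kept)\n", x$thresholds$sample_missing_max))
  cat("  retained:", x$retained$samples, "samples x", x$retained$snps,
      "SNPs\n")
  invisible(x)
}

#' Export a QC report
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return invisibly, `path`.
#' @export
write_qc_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    df <- data.frame(
      metric = c(names(report$removed), "retained_samples", "retained_snps"),
      value = c(unlist(report$removed), report$retained$samples,
                report$retained$snps))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
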