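#' Filter a panel down to informative SNPs
#'
#' A SNP is non-informative when (1) it has no genome position, (2)
#' heterozygous-or-missing calls exceed `max_missing_fraction` of all
#' accessions (strictly more than; heterozygotes were already coerced to
#' missing at load), or (3) its minor-allele frequency among non-missing
#' calls is at or below `min_allele_freq` (a genotyping-error guard, so
#' the boundary is inclusive: exactly 2% is removed). Dispositions are
#' mutually exclusive; the first failing criterion in the order 1, 2, 3
#' labels the SNP, though the retained set itself does not depend on the
#' order.
#'
#' @param x a `geno_matrix`
#' @param max_missing_fraction criterion-2 threshold (default 0.5)
#' @param min_allele_freq criterion-3 threshold (default 0.02)
#' @return list with `panel` (filtered `geno_matrix`) and `report`
#'   (a `qc_report`: counts plus a per-SNP disposition table)
#' @export
filter_informative <- function(x, max_missing_fraction = 0.5,
                               min_allele_freq = 0.02) {
  stopifnot(inherits(x, "geno_matrix"))
  n_acc <- nrow(x$calls)
  no_pos <- is.na(x$snps$position_bp) | is.na(x$snps$chromosome)
  miss_frac <- colMeans(is.na(x$calls))
  n_b <- colSums(x$calls == "B", na.rm = TRUE)
  n_ok <- colSums(!is.na(x$calls))
  maf <- ifelse(n_ok > 0, pmin(n_b, n_ok - n_b) / n_ok, 0)

  disposition <- rep("informative", ncol(x$calls))
  disposition[maf <= min_allele_freq] <- "rare_allele"
  disposition[miss_frac > max_missing_fraction] <- "missing_het"
  disposition[no_pos] <- "no_position"

  keep <- disposition == "informative"
  if (!any(keep)) stop("empty panel: no SNP passed the informativeness criteria")

  report <- structure(
    list(
      n_input = ncol(x$calls),
      n_removed_no_position = sum(disposition == "no_position"),
      n_removed_missing_het = sum(disposition == "missing_het"),
      n_removed_rare = sum(disposition == "rare_allele"),
      n_informative = sum(keep),
      max_missing_fraction = max_missing_fraction,
      min_allele_freq = min_allele_freq,
      dispositions = data.frame(
        snp_id = x$snps$snp_id,
        disposition = disposition,
        missing_fraction = miss_frac,
        minor_allele_freq = maf,
        stringsAsFactors = FALSE
      )
    ),
    class = "qc_report"
  )
  list(panel = geno_subset(x, snps = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP informativeness report\n")
  cat(sprintf("  input SNPs:           %6d\n", x$n_input))
  cat(sprintf("  removed, no position: %6d\n", x$n_removed_no_position))
  cat(sprintf("  removed, >%.0f%% missing/het: %d\n",
              100 * x$max_missing_fraction, x$n_removed_missing_het))
  cat(sprintf("  removed, MAF <= %.0f%%: %6d\n",
              100 * x$min_allele_freq, x$n_removed_rare))
  cat(sprintf("  informative:          %6d\n", x$n_informative))
  invisible(x)
}

#' Write a QC disposition table as CSV
#'
#' @param report a `qc_report`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(report$dispositions, path, row.names = FALSE)
  invisible(path)
}
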