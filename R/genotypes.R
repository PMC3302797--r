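#' Genotype matrix for inbred biallelic SNP panels
#'
#' The central container of the package: an accession x SNP table of
#' homozygous biallelic calls with an explicit missing mask. Calls are
#' stored as `"A"`/`"B"` character codes (allele labels are arbitrary and
#' every statistic in the package is invariant to swapping them) with `NA`
#' for missing. Heterozygous input calls are coerced to missing at read
#' time because the panels this package targets are effectively homozygous
#' inbred lines, where a heterozygous signal is treated as no signal.
#'
#' @param calls character matrix (accessions x SNPs) over `"A"`, `"B"`, `NA`.
#'   Row names are accession ids, column names SNP ids.
#' @param snps data frame with columns `snp_id`, `chromosome` (integer),
#'   `position_bp` (integer, 1-based; may be `NA` for unmapped SNPs),
#'   `source_panel` (character). Internally sorted by
#'   `(chromosome, position_bp)`, unmapped SNPs last.
#' @param accessions data frame with columns `accession_id`, `group`
#'   (one of `"group1"`, `"group2"`, `"group3"`, `"foreign"`),
#'   `water_regime` (`"irrigated"` or `"non_irrigated"`),
#'   `registration_year` (integer or `NA`), `region` (character or `NA`).
#' @param n_het_coerced number of heterozygous calls coerced to missing
#'   when the matrix was loaded.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `snps`, `accessions`, `n_het_coerced`.
#' @export
geno_matrix <- function(calls, snps, accessions, n_het_coerced = 0L) {
  stopifnot(is.matrix(calls), is.data.frame(snps), is.data.frame(accessions))
  req_snp <- c("snp_id", "chromosome", "position_bp", "source_panel")
  if (!all(req_snp %in% names(snps))) {
    stop("snps metadata must have columns: ", paste(req_snp, collapse = ", "))
  }
  req_acc <- c("accession_id", "group", "water_regime", "registration_year", "region")
  if (!all(req_acc %in% names(accessions))) {
    stop("accession metadata must have columns: ", paste(req_acc, collapse = ", "))
  }
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.integer(snps$chromosome)
  snps$position_bp <- as.integer(snps$position_bp)
  accessions$accession_id <- as.character(accessions$accession_id)

  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id in SNP metadata: ",
         snps$snp_id[duplicated(snps$snp_id)][1])
  }
  if (anyDuplicated(accessions$accession_id)) {
    stop("duplicate accession_id: ",
         accessions$accession_id[duplicated(accessions$accession_id)][1])
  }
  bad_grp <- setdiff(unique(accessions$group),
                     c("group1", "group2", "group3", "foreign"))
  if (length(bad_grp)) stop("unknown accession group: ", bad_grp[1])
  bad_reg <- setdiff(unique(accessions$water_regime),
                     c("irrigated", "non_irrigated"))
  if (length(bad_reg)) stop("unknown water_regime: ", bad_reg[1])
  g3 <- accessions$group == "group3"
  if (any(g3 & accessions$water_regime != "irrigated")) {
    stop("group3 accessions must be irrigated")
  }

  if (nrow(calls) != nrow(accessions) || ncol(calls) != nrow(snps)) {
    stop("calls dimensions (", nrow(calls), " x ", ncol(calls),
         ") do not match metadata (", nrow(accessions), " accessions, ",
         nrow(snps), " SNPs)")
  }
  if (is.null(rownames(calls))) rownames(calls) <- accessions$accession_id
  if (is.null(colnames(calls))) colnames(calls) <- snps$snp_id
  if (!identical(rownames(calls), accessions$accession_id)) {
    stop("call matrix row names do not match accession metadata order")
  }
  if (!identical(colnames(calls), snps$snp_id)) {
    stop("call matrix column names do not match SNP metadata order")
  }
  bad <- setdiff(unique(as.vector(calls)), c("A", "B", NA))
  if (length(bad)) stop("call matrix may only contain 'A', 'B', NA; found: ", bad[1])

  # position ties make window identity ambiguous: reject rather than reorder
  mapped <- !is.na(snps$position_bp) & !is.na(snps$chromosome)
  key <- paste(snps$chromosome[mapped], snps$position_bp[mapped])
  if (anyDuplicated(key)) {
    stop("tied SNP positions within a chromosome: ",
         snps$snp_id[mapped][duplicated(key)][1])
  }
  ord <- order(!mapped, snps$chromosome, snps$position_bp)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  calls <- calls[, ord, drop = FALSE]

  structure(
    list(calls = calls, snps = snps, accessions = accessions,
         n_het_coerced = as.integer(n_het_coerced)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "accessions x", ncol(x$calls), "SNPs\n")
  cat("  chromosomes:", length(unique(stats::na.omit(x$snps$chromosome))),
      " | unmapped SNPs:", sum(is.na(x$snps$position_bp)), "\n")
  tb <- table(x$accessions$group, x$accessions$water_regime)
  print(tb)
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%  (het coerced at load: %d)\n",
              100 * miss, x$n_het_coerced))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by accessions and/or SNPs
#'
#' @param x a `geno_matrix`
#' @param accessions character vector of accession ids, or logical/integer
#'   index over rows; `NULL` keeps all
#' @param snps character vector of SNP ids, or logical/integer index over
#'   columns; `NULL` keeps all
#' @return a `geno_matrix`
#' @export
geno_subset <- function(x, accessions = NULL, snps = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  ri <- seq_len(nrow(x$calls))
  ci <- seq_len(ncol(x$calls))
  if (!is.null(accessions)) {
    ri <- if (is.character(accessions)) {
      m <- match(accessions, x$accessions$accession_id)
      if (anyNA(m)) stop("unknown accession id: ", accessions[is.na(m)][1])
      m
    } else which(rep_len(TRUE, nrow(x$calls)))[accessions]
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) {
      m <- match(snps, x$snps$snp_id)
      if (anyNA(m)) stop("unknown snp id: ", snps[is.na(m)][1])
      m
    } else which(rep_len(TRUE, ncol(x$calls)))[snps]
  }
  geno_matrix(x$calls[ri, ci, drop = FALSE],
              x$snps[ci, , drop = FALSE],
              x$accessions[ri, , drop = FALSE],
              n_het_coerced = x$n_het_coerced)
}

#' Accession ids belonging to a breeding-phase group
#'
#' By convention the cross-group analyses of this package (diversity
#' indices, LD profiles, novel polymorphisms) are run on irrigated
#' accessions only, because non-irrigated material forms a genetically
#' separate population whose inclusion would confound breeding-phase
#' contrasts.
#'
#' @param x a `geno_matrix`
#' @param group group label (`"group1"`, `"group2"`, `"group3"`, `"foreign"`)
#' @param irrigated_only drop non-irrigated accessions (default `TRUE`)
#' @return character vector of accession ids
#' @export
group_members <- function(x, group, irrigated_only = TRUE) {
  stopifnot(inherits(x, "geno_matrix"))
  a <- x$accessions
  keep <- a$group == group
  if (irrigated_only) keep <- keep & a$water_regime == "irrigated"
  a$accession_id[keep]
}

# row indices for a set of accession ids
.acc_rows <- function(x, ids) {
  m <- match(ids, x$accessions$accession_id)
  if (anyNA(m)) stop("unknown accession id: ", ids[is.na(m)][1])
  m
}
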