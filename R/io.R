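#' Read a genotype panel from tab-delimited tables
#'
#' Loads an accession x SNP call table plus SNP and accession metadata.
#' Cells are raw allele symbols; per SNP the two observed symbols are
#' mapped to `"A"`/`"B"` in order of first appearance down the file (every
#' statistic in the package is invariant to this labelling). Heterozygous
#' cells are coerced to missing and counted.
#'
#' @param path genotype TSV: first column accession id, remaining columns
#'   one per SNP (header = SNP ids); cells are allele symbols, the
#'   heterozygote code or the missing code.
#' @param snp_meta_path TSV with columns `snp_id`, `chromosome`,
#'   `position_bp`, `source_panel` (chromosome/position may be empty for
#'   unmapped SNPs).
#' @param accession_meta_path TSV with columns `accession_id`, `group`,
#'   `water_regime`, `registration_year`, `region`.
#' @param het_code,missing_code cell codes treated as heterozygous /
#'   missing (defaults `"H"` and `"N"`).
#' @return a [geno_matrix()]
#' @export
read_genotype_table <- function(path, snp_meta_path, accession_meta_path,
                                het_code = "H", missing_code = "N") {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "")
  snps <- read_snp_meta(snp_meta_path)
  accs <- read_accession_meta(accession_meta_path)

  acc_ids <- raw[[1]]
  g <- as.matrix(raw[, -1, drop = FALSE])
  rownames(g) <- acc_ids

  unknown_acc <- setdiff(acc_ids, accs$accession_id)
  if (length(unknown_acc)) {
    stop("accession in genotype table but not in metadata: ", unknown_acc[1])
  }
  unknown_snp <- setdiff(colnames(g), snps$snp_id)
  if (length(unknown_snp)) {
    stop("SNP in genotype table but not in metadata: ", unknown_snp[1])
  }
  accs <- accs[match(acc_ids, accs$accession_id), , drop = FALSE]
  rownames(accs) <- NULL
  snps <- snps[match(colnames(g), snps$snp_id), , drop = FALSE]
  rownames(snps) <- NULL

  n_het <- sum(g == het_code, na.rm = TRUE)
  g[g == het_code | g == missing_code | g == ""] <- NA

  calls <- matrix(NA_character_, nrow(g), ncol(g),
                  dimnames = dimnames(g))
  for (j in seq_len(ncol(g))) {
    col <- g[, j]
    sym <- unique(col[!is.na(col)])
    if (length(sym) > 2) {
      stop("non-biallelic SNP column '", colnames(g)[j], "': symbols ",
           paste(sym, collapse = ","))
    }
    if (all(sym %in% c("A", "B"))) {
      # already in canonical codes: keep them, so write/read round-trips
      calls[, j] <- col
    } else {
      if (length(sym) >= 1) calls[col == sym[1] & !is.na(col), j] <- "A"
      if (length(sym) == 2) calls[col == sym[2] & !is.na(col), j] <- "B"
    }
  }
  geno_matrix(calls, snps, accs, n_het_coerced = n_het)
}

read_snp_meta <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  req <- c("snp_id", "chromosome", "position_bp", "source_panel")
  if (!all(req %in% names(m))) {
    stop("SNP metadata must have columns: ", paste(req, collapse = ", "))
  }
  m$chromosome <- suppressWarnings(as.integer(m$chromosome))
  m$position_bp <- suppressWarnings(as.integer(m$position_bp))
  m[, req, drop = FALSE]
}

read_accession_meta <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         na.strings = c("NA", ""))
  req <- c("accession_id", "group", "water_regime", "registration_year", "region")
  if (!all(req %in% names(m))) {
    stop("accession metadata must have columns: ", paste(req, collapse = ", "))
  }
  m$registration_year <- suppressWarnings(as.integer(m$registration_year))
  m[, req, drop = FALSE]
}

#' Write a genotype panel as the package's tab-delimited formats
#'
#' Inverse of [read_genotype_table()]: writes the call table (codes `A`,
#' `B`, `N`), the SNP metadata and the accession metadata. A write/read
#' round trip reproduces calls, order and metadata exactly.
#'
#' @param x a `geno_matrix`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix (default `"panel"`)
#' @return invisibly, the three file paths written
#' @export
write_genotype_table <- function(x, dir, prefix = "panel") {
  stopifnot(inherits(x, "geno_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gpath <- file.path(dir, paste0(prefix, "_genotypes.tsv"))
  spath <- file.path(dir, paste0(prefix, "_snps.tsv"))
  apath <- file.path(dir, paste0(prefix, "_accessions.tsv"))

  g <- x$calls
  g[is.na(g)] <- "N"
  df <- data.frame(accession_id = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$snps, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$accessions, apath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotypes = gpath, snps = spath, accessions = apath))
}

#' Read genotypes from a VCF file
#'
#' Converts homozygous GT fields to the internal biallelic coding:
#' `0/0` (or `0|0`) becomes allele A, `1/1` allele B; heterozygous and
#' missing genotypes become missing calls. Records with more than one ALT
#' allele are skipped with a message.
#'
#' @param path VCF 4.x file with a GT FORMAT field
#' @param accession_meta_path accession metadata TSV (see
#'   [read_genotype_table()]); VCF samples absent from it are dropped
#' @param source_panel value recorded as the SNPs' source panel
#' @return a [geno_matrix()]
#' @export
read_vcf <- function(path, accession_meta_path, source_panel = "other") {
  accs <- read_accession_meta(accession_meta_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("no usable records in VCF: ", path)

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  n_skipped <- sum(multi)
  if (n_skipped > 0) {
    message("skipping ", n_skipped, " multi-allelic VCF record(s)")
  }
  if (all(multi)) stop("no usable records in VCF: ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]

  samples <- colnames(gt)
  common <- intersect(samples, accs$accession_id)
  if (length(common) == 0) stop("no VCF samples found in accession metadata")
  gt <- gt[, common, drop = FALSE]

  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_character_, nrow(gt_norm), ncol(gt_norm))
  calls[gt_norm == "0/0" | gt_norm == "0"] <- "A"
  calls[gt_norm == "1/1" | gt_norm == "1"] <- "B"
  n_het <- sum(gt_norm %in% c("0/1", "1/0"))

  ids <- fix$ID
  if (is.null(ids) || anyNA(ids) || any(ids == ".")) {
    ids <- paste0(fix$CHROM, "_", fix$POS)
  }
  snps <- data.frame(
    snp_id = ids,
    chromosome = as.integer(gsub("^[Cc]hr0?", "", fix$CHROM)),
    position_bp = as.integer(fix$POS),
    source_panel = source_panel,
    stringsAsFactors = FALSE
  )
  calls <- t(calls)
  rownames(calls) <- common
  colnames(calls) <- snps$snp_id
  accs <- accs[match(common, accs$accession_id), , drop = FALSE]
  rownames(accs) <- NULL
  geno_matrix(calls, snps, accs, n_het_coerced = n_het)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write genomic intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so a stored interval `[start, end]` is written as `start-1`, `end`.
#'
#' @param intervals data frame with columns `chromosome`, `start_bp`,
#'   `end_bp` and optionally `label`
#' @param path output file
#' @param chrom_prefix prefix for the chromosome column (default `"chr"`)
#' @return invisibly, `path`
#' @export
write_bed <- function(intervals, path, chrom_prefix = "chr") {
  if (nrow(intervals) == 0) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(intervals$start_bp <= intervals$end_bp))
  lab <- if ("label" %in% names(intervals)) intervals$label else NULL
  df <- data.frame(chrom = paste0(chrom_prefix, intervals$chromosome),
                   start = intervals$start_bp - 1L,
                   end = intervals$end_bp)
  if (!is.null(lab)) df$name <- lab
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read annotation intervals from a BED-like file
#'
#' Expects BED3 plus two extra columns: `label` and `kind` (one of
#' `"qtl"`, `"gene"`, `"centromere"`). BED's 0-based half-open coordinates
#' are converted to the package's 1-based inclusive convention.
#'
#' @param path input file (tab-separated, no header)
#' @return data frame with columns `chromosome`, `start_bp`, `end_bp`,
#'   `label`, `kind`
#' @export
read_annotations <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(raw) < 3) stop("annotation BED needs at least 3 columns")
  out <- data.frame(
    chromosome = as.integer(gsub("^[Cc]hr0?", "", raw[[1]])),
    start_bp = as.integer(raw[[2]]) + 1L,
    end_bp = as.integer(raw[[3]]),
    label = if (ncol(raw) >= 4) raw[[4]] else paste0("iv", seq_len(nrow(raw))),
    kind = if (ncol(raw) >= 5) raw[[5]] else "qtl",
    stringsAsFactors = FALSE
  )
  if (any(out$start_bp > out$end_bp)) stop("annotation interval with start > end")
  bad <- setdiff(unique(out$kind), c("qtl", "gene", "centromere"))
  if (length(bad)) stop("unknown annotation kind: ", bad[1])
  out
}

#' Read an admixture Q-matrix
#'
#' @param path TSV: first column accession id, remaining columns one per
#'   ancestral component (header gives component names)
#' @param tol tolerance for the row-sum-to-one check
#' @return numeric matrix (accessions x components) with row/column names
#' @export
read_qmatrix <- function(path, tol = 1e-6) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  q <- as.matrix(raw[, -1, drop = FALSE])
  rownames(q) <- as.character(raw[[1]])
  storage.mode(q) <- "double"
  if (any(q < 0 | q > 1)) stop("Q-matrix entries must lie in [0, 1]")
  if (any(abs(rowSums(q) - 1) > tol)) {
    stop("Q-matrix rows must sum to 1 (tolerance ", tol, ")")
  }
  q
}

#' Read pedigree records
#'
#' @param path TSV with columns `child`, `parent1`, `parent2`,
#'   `recurrent_parent` (empty/NA where not a backcross; otherwise must
#'   name one of the two parents). Parents may be empty for founders.
#' @return data frame of class `pedigree_df`
#' @export
read_pedigree <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", na.strings = c("NA", ""))
  req <- c("child", "parent1", "parent2", "recurrent_parent")
  if (!all(req %in% names(p))) {
    stop("pedigree must have columns: ", paste(req, collapse = ", "))
  }
  validate_pedigree(p[, req, drop = FALSE])
}

validate_pedigree <- function(p) {
  rec <- !is.na(p$recurrent_parent)
  ok <- !rec | p$recurrent_parent == p$parent1 |
    p$recurrent_parent == p$parent2
  if (!all(ok, na.rm = TRUE)) {
    stop("recurrent_parent must name parent1 or parent2 (child ",
         p$child[!ok][1], ")")
  }
  class(p) <- c("pedigree_df", "data.frame")
  p
}
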