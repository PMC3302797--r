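#' Find SNP alleles absent from the reference breeding phase
#'
#' A SNP is reported when every non-missing call in the reference group is
#' the same allele and the other allele appears in at least one of the
#' later groups (union reading; the per-group frequencies let a
#' both-groups filter be applied afterwards). SNPs with no non-missing
#' reference call are skipped and counted in the `"n_skipped"` attribute.
#'
#' @param x a QC'd `geno_matrix`
#' @param reference_group reference group label (default `"group1"`)
#' @param later_groups later group labels (default groups 2 and 3)
#' @param irrigated_only restrict to irrigated accessions (default `TRUE`)
#' @return data frame: `snp_id`, `chromosome`, `position_bp`,
#'   `novel_allele`, `freq_group2`, ... (one frequency column per later
#'   group, novel-allele frequency among its non-missing calls)
#' @export
find_novel_snps <- function(x, reference_group = "group1",
                            later_groups = c("group2", "group3"),
                            irrigated_only = TRUE) {
  ref_rows <- .acc_rows(x, group_members(x, reference_group, irrigated_only))
  later_rows <- lapply(later_groups, function(g) {
    .acc_rows(x, group_members(x, g, irrigated_only))
  })
  names(later_rows) <- later_groups

  ref <- x$calls[ref_rows, , drop = FALSE]
  ref_a <- colSums(ref == "A", na.rm = TRUE)
  ref_b <- colSums(ref == "B", na.rm = TRUE)
  n_skipped <- sum(ref_a + ref_b == 0)
  mono <- (ref_a == 0) != (ref_b == 0)  # exactly one allele seen
  novel_allele <- ifelse(ref_b == 0, "B", "A")

  freqs <- lapply(later_rows, function(rows) {
    sub <- x$calls[rows, , drop = FALSE]
    cnt <- colSums(sub == rep(novel_allele, each = length(rows)), na.rm = TRUE)
    tot <- colSums(!is.na(sub))
    list(count = cnt, freq = ifelse(tot > 0, cnt / tot, 0))
  })
  seen_later <- Reduce(`+`, lapply(freqs, `[[`, "count")) > 0
  hit <- which(mono & seen_later)

  out <- data.frame(
    snp_id = x$snps$snp_id[hit],
    chromosome = x$snps$chromosome[hit],
    position_bp = x$snps$position_bp[hit],
    novel_allele = novel_allele[hit],
    stringsAsFactors = FALSE
  )
  for (g in later_groups) out[[paste0("freq_", g)]] <- freqs[[g]]$freq[hit]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Count a cultivar's haplotype-block strings unseen in the reference group
#'
#' For each block, the cultivar contributes 1 when its complete five-call
#' window string is absent from the set of complete window strings of the
#' reference group. Windows where the cultivar has a missing call, or
#' where the reference group has no complete string at all, contribute 0
#' (the latter are counted in attribute `"n_ref_empty"`). A single new SNP
#' allele perturbs every window containing it, so one mutation typically
#' adds `window` (five) counts.
#'
#' @param x a `geno_matrix`
#' @param blocks table from [enumerate_blocks()]
#' @param reference_group reference group label (default `"group1"`), or a
#'   character vector of accession ids to use directly
#' @param cultivars accession ids to count; defaults to all irrigated
#'   accessions outside the reference group with a known registration year
#' @param irrigated_only restrict group lookups to irrigated accessions
#' @return data frame: `accession_id`, `group`, `registration_year`,
#'   `n_novel`
#' @export
count_novel_block_haplotypes <- function(x, blocks,
                                         reference_group = "group1",
                                         cultivars = NULL,
                                         irrigated_only = TRUE) {
  ref_ids <- if (length(reference_group) == 1 &&
                 reference_group %in% c("group1", "group2", "group3", "foreign")) {
    group_members(x, reference_group, irrigated_only)
  } else reference_group
  if (is.null(cultivars)) {
    a <- x$accessions
    keep <- !(a$accession_id %in% ref_ids) & !is.na(a$registration_year)
    if (irrigated_only) keep <- keep & a$water_regime == "irrigated"
    cultivars <- a$accession_id[keep]
  }
  if (any(cultivars %in% ref_ids)) {
    stop("cultivar is a member of the reference group: ",
         intersect(cultivars, ref_ids)[1])
  }
  s <- window_strings(x, blocks)
  ref_s <- s[.acc_rows(x, ref_ids), , drop = FALSE]
  cult_rows <- .acc_rows(x, cultivars)
  counts <- integer(length(cultivars))
  n_ref_empty <- 0L
  for (j in seq_len(ncol(s))) {
    refset <- unique(ref_s[, j])
    refset <- refset[!is.na(refset)]
    if (length(refset) == 0) {
      n_ref_empty <- n_ref_empty + 1L
      next
    }
    v <- s[cult_rows, j]
    counts <- counts + (!is.na(v) & !(v %in% refset))
  }
  out <- data.frame(
    accession_id = cultivars,
    group = x$accessions$group[cult_rows],
    registration_year = x$accessions$registration_year[cult_rows],
    n_novel = counts,
    stringsAsFactors = FALSE
  )
  attr(out, "n_ref_empty") <- n_ref_empty
  out
}

#' Fit the novel-polymorphism accrual regression
#'
#' Ordinary least squares of the per-cultivar novel-haplotype count on
#' registration year (`y = a + b x + e`): the slope is the rate at which
#' new haplotype polymorphisms accumulate per year of breeding.
#'
#' @param counts data frame with columns `registration_year` and
#'   `n_novel` (e.g. from [count_novel_block_haplotypes()]); rows with
#'   missing year are dropped
#' @return object of class `hap_accrual`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `slope_se`, `n_cultivars`, `data`, and the
#'   underlying `lm` fit in `fit`
#' @export
fit_accrual <- function(counts) {
  d <- counts[!is.na(counts$registration_year) & !is.na(counts$n_novel), ,
              drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 cultivars with a registration year")
  if (length(unique(d$registration_year)) < 2) {
    stop("degenerate design: all registration years identical")
  }
  fit <- stats::lm(n_novel ~ registration_year, data = d)
  sm <- suppressWarnings(summary(fit))  # exact lines are legitimate here
  r2 <- if (stats::var(d$n_novel) == 0) 0 else sm$r.squared
  p <- if (stats::var(d$n_novel) == 0) 1 else sm$coefficients[2, 4]
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         slope_se = sm$coefficients[2, 2],
         r_squared = r2,
         p_value = p,
         n_cultivars = nrow(d),
         data = d,
         fit = fit),
    class = "hap_accrual"
  )
}

#' @export
print.hap_accrual <- function(x, ...) {
  cat("novel-polymorphism accrual regression (OLS)\n")
  cat(sprintf("  %d cultivars, years %d-%d\n", x$n_cultivars,
              min(x$data$registration_year), max(x$data$registration_year)))
  cat(sprintf("  slope: %.3f new polymorphisms / year (SE %.3f)\n",
              x$slope, x$slope_se))
  cat(sprintf("  intercept: %.1f | R^2 = %.3f | p = %.3g\n",
              x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' @export
summary.hap_accrual <- function(object, ...) summary(object$fit, ...)

#' @export
coef.hap_accrual <- function(object, ...) stats::coef(object$fit)

#' @export
predict.hap_accrual <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit, ...))
  if (!is.data.frame(newdata)) {
    newdata <- data.frame(registration_year = newdata)
  }
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.hap_accrual <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.hap_accrual <- function(x, ...) {
  graphics::plot(x$data$registration_year, x$data$n_novel,
                 xlab = "registration year",
                 ylab = "novel haplotype polymorphisms", ...)
  graphics::abline(x$fit, col = 2)
  invisible(NULL)
}
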