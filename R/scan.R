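#' Compare block diversity indices between two groups
#'
#' Counts, over blocks at identical positions, how often each group shows
#' the higher diversity index, plus ties, and tests the two lists of
#' indices with a two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param census_a,census_b per-block census tables for the two groups
#'   (rows of [census_all()] output restricted to one group each), covering
#'   identical block sets
#' @return object of class `group_comparison`: list with `groups`,
#'   `n_blocks`, `n_higher_in_first`, `n_higher_in_second`, `n_ties`,
#'   `mannwhitney_p`
#' @export
compare_groups <- function(census_a, census_b) {
  if (!setequal(census_a$block_id, census_b$block_id) ||
      nrow(census_a) != nrow(census_b)) {
    stop("censuses do not cover identical block sets")
  }
  census_b <- census_b[match(census_a$block_id, census_b$block_id), ,
                       drop = FALSE]
  ia <- census_a$diversity_index
  ib <- census_b$diversity_index
  p <- suppressWarnings(
    stats::wilcox.test(ia, ib, alternative = "two.sided")$p.value
  )
  structure(
    list(groups = c(unique(census_a$group)[1], unique(census_b$group)[1]),
         n_blocks = length(ia),
         n_higher_in_first = sum(ia > ib),
         n_higher_in_second = sum(ib > ia),
         n_ties = sum(ia == ib),
         mannwhitney_p = p),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("diversity comparison %s vs %s over %d blocks\n",
              x$groups[1], x$groups[2], x$n_blocks))
  cat(sprintf("  higher in %s: %d | higher in %s: %d | ties: %d\n",
              x$groups[1], x$n_higher_in_first,
              x$groups[2], x$n_higher_in_second, x$n_ties))
  cat(sprintf("  Mann-Whitney p = %.3g\n", x$mannwhitney_p))
  invisible(x)
}

#' Flag blocks whose diversity collapsed in later breeding phases
#'
#' A block is flagged when both later groups hold strictly fewer than
#' `ratio` times the reference group's number of distinct haplotypes
#' (raw counts, not indices, since the group sizes differ; set
#' `use_index = TRUE` for the normalised variant). Blocks where the
#' reference count is zero, or where any group has no complete-case
#' accession, are never flagged.
#'
#' @param census_g1,census_g2,census_g3 per-block censuses of the
#'   reference group and the two later groups, over identical block sets
#' @param ratio collapse threshold (default 0.5, i.e. "less than half")
#' @param use_index compare diversity indices instead of raw counts
#' @return integer vector of flagged `block_id`s
#' @export
flag_reduced_blocks <- function(census_g1, census_g2, census_g3,
                                ratio = 0.5, use_index = FALSE) {
  if (!setequal(census_g1$block_id, census_g2$block_id) ||
      !setequal(census_g1$block_id, census_g3$block_id)) {
    stop("censuses do not cover identical block sets")
  }
  census_g2 <- census_g2[match(census_g1$block_id, census_g2$block_id), ]
  census_g3 <- census_g3[match(census_g1$block_id, census_g3$block_id), ]
  v <- if (use_index) "diversity_index" else "n_distinct_haplotypes"
  n1 <- census_g1[[v]]
  n2 <- census_g2[[v]]
  n3 <- census_g3[[v]]
  usable <- census_g1$n_distinct_haplotypes > 0 &
    census_g1$n_complete > 0 & census_g2$n_complete > 0 &
    census_g3$n_complete > 0
  flagged <- usable & (n2 < ratio * n1) & (n3 < ratio * n1)
  census_g1$block_id[flagged]
}

#' Merge flagged blocks into reduced-diversity regions
#'
#' Maximal runs of flagged blocks with consecutive window indices on one
#' chromosome (i.e. adjacent windows sharing four SNPs) are merged into a
#' region spanning the first SNP of the first block to the last SNP of the
#' last block. Runs shorter than `min_blocks` are dropped.
#'
#' @param blocks table from [enumerate_blocks()]
#' @param flagged_ids integer vector from [flag_reduced_blocks()]
#' @param min_blocks minimum run length to emit (default 2; use 1 to keep
#'   singletons)
#' @return data frame: `region_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `n_blocks`, `length_kb`, `first_block_id`, `last_block_id`
#' @export
merge_regions <- function(blocks, flagged_ids, min_blocks = 2L) {
  fl <- blocks[blocks$block_id %in% flagged_ids, , drop = FALSE]
  empty <- data.frame(region_id = integer(), chromosome = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_blocks = integer(), length_kb = numeric(),
                      first_block_id = integer(), last_block_id = integer())
  if (nrow(fl) == 0) return(empty)
  fl <- fl[order(fl$block_id), , drop = FALSE]
  new_run <- c(TRUE, diff(fl$block_id) != 1L |
                 diff(fl$chromosome) != 0L)
  run <- cumsum(new_run)
  out <- lapply(split(fl, run), function(r) {
    data.frame(chromosome = r$chromosome[1],
               start_bp = r$start_bp[1],
               end_bp = r$end_bp[nrow(r)],
               n_blocks = nrow(r),
               first_block_id = r$block_id[1],
               last_block_id = r$block_id[nrow(r)])
  })
  res <- do.call(rbind, out)
  res <- res[res$n_blocks >= min_blocks, , drop = FALSE]
  if (nrow(res) == 0) return(empty)
  res$length_kb <- (res$end_bp - res$start_bp) / 1000
  res <- res[order(res$chromosome, res$start_bp), , drop = FALSE]
  res <- cbind(region_id = seq_len(nrow(res)), res)
  res <- res[, c("region_id", "chromosome", "start_bp", "end_bp",
                 "n_blocks", "length_kb", "first_block_id", "last_block_id")]
  rownames(res) <- NULL
  res
}

#' Overlay annotation intervals on reduced-diversity regions
#'
#' An annotation co-localises with a region when their closed 1-based
#' intervals overlap by at least one base pair on the same chromosome
#' (an annotation ending exactly at the region start counts).
#'
#' @param regions table from [merge_regions()]
#' @param annotations data frame from [read_annotations()] (columns
#'   `chromosome`, `start_bp`, `end_bp`, `label`, `kind`)
#' @return `regions` with added columns `n_qtl`, `n_gene`, `labels`
#'   (comma-separated overlapping annotation labels)
#' @export
annotate_regions <- function(regions, annotations) {
  regions$n_qtl <- 0L
  regions$n_gene <- 0L
  regions$labels <- ""
  if (nrow(regions) == 0 || nrow(annotations) == 0) return(regions)
  for (i in seq_len(nrow(regions))) {
    hit <- annotations$chromosome == regions$chromosome[i] &
      annotations$start_bp <= regions$end_bp[i] &
      annotations$end_bp >= regions$start_bp[i]
    regions$n_qtl[i] <- sum(hit & annotations$kind == "qtl")
    regions$n_gene[i] <- sum(hit & annotations$kind == "gene")
    regions$labels[i] <- paste(annotations$label[hit], collapse = ",")
  }
  regions
}
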