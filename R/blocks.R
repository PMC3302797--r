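#' Enumerate sliding haplotype-block windows
#'
#' A haplotype block is a window of `window` consecutive SNPs on one
#' chromosome, slid one SNP at a time, so a chromosome carrying `n` mapped
#' SNPs yields `max(0, n - window + 1)` blocks and no window spans a
#' chromosome end. With the default five-SNP window, a 3259-SNP map over
#' 12 chromosomes yields 3259 - 4 x 12 = 3211 blocks.
#'
#' @param snps SNP metadata data frame (`snp_id`, `chromosome`,
#'   `position_bp`), already sorted by `(chromosome, position_bp)` as in a
#'   `geno_matrix`; unmapped SNPs (`NA` position) are ignored.
#' @param window window size in SNPs (default 5)
#' @return data frame with one row per block: `block_id` (genome-wide,
#'   ordered), `chromosome`, `start_idx` (column index of the first SNP in
#'   `snps`), `start_bp`, `end_bp`, `snp_first`, `snp_last`
#' @export
enumerate_blocks <- function(snps, window = 5L) {
  stopifnot(window >= 2)
  mapped <- which(!is.na(snps$position_bp) & !is.na(snps$chromosome))
  out <- list()
  for (chr in unique(snps$chromosome[mapped])) {
    idx <- mapped[snps$chromosome[mapped] == chr]
    n <- length(idx)
    if (n < window) next
    starts <- idx[seq_len(n - window + 1L)]
    ends <- idx[seq.int(window, n)]
    out[[length(out) + 1L]] <- data.frame(
      chromosome = chr,
      start_idx = starts,
      start_bp = snps$position_bp[starts],
      end_bp = snps$position_bp[ends],
      snp_first = snps$snp_id[starts],
      snp_last = snps$snp_id[ends],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(block_id = integer(), chromosome = integer(),
                      start_idx = integer(), start_bp = integer(),
                      end_bp = integer(), snp_first = character(),
                      snp_last = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start_bp), , drop = FALSE]
  res <- cbind(block_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  attr(res, "window") <- as.integer(window)
  res
}

# accession x block matrix of concatenated window call strings;
# NA wherever any of the window's calls is missing
window_strings <- function(x, blocks) {
  window <- attr(blocks, "window") %||% 5L
  calls <- x$calls
  n <- nrow(calls)
  nb <- nrow(blocks)
  if (nb == 0) return(matrix(character(), n, 0))
  idx0 <- blocks$start_idx
  parts <- vector("list", window)
  miss <- matrix(FALSE, n, nb)
  for (k in seq_len(window)) {
    sub <- calls[, idx0 + (k - 1L), drop = FALSE]
    miss <- miss | is.na(sub)
    parts[[k]] <- sub
  }
  s <- matrix(do.call(paste0, parts), n, nb)
  s[miss] <- NA_character_
  rownames(s) <- rownames(calls)
  s
}

#' Census of distinct haplotypes in one block for one group
#'
#' Counts the distinct window call strings ("polymorphisms" of the block)
#' among the group's accessions that have all `window` calls non-missing,
#' and divides by the group size to give the diversity index. The
#' denominator is the full group size, not the complete-case count; set
#' `complete_case_denominator = TRUE` for the alternative normalisation.
#'
#' @param x a `geno_matrix`
#' @param block one row of the [enumerate_blocks()] table
#' @param group_ids character vector of accession ids forming the group
#' @param complete_case_denominator divide by the number of complete-case
#'   accessions instead of the group size (default `FALSE`)
#' @return one-row data frame: `block_id`, `n_group`, `n_complete`,
#'   `n_distinct_haplotypes`, `diversity_index`
#' @export
census_block <- function(x, block, group_ids,
                         complete_case_denominator = FALSE) {
  if (length(group_ids) == 0) stop("empty group")
  blocks1 <- block
  attr(blocks1, "window") <- attr(block, "window") %||% 5L
  s <- window_strings(x, blocks1)[.acc_rows(x, group_ids), 1]
  ok <- !is.na(s)
  ndist <- length(unique(s[ok]))
  denom <- if (complete_case_denominator) max(sum(ok), 1L) else length(group_ids)
  data.frame(block_id = block$block_id,
             n_group = length(group_ids),
             n_complete = sum(ok),
             n_distinct_haplotypes = ndist,
             diversity_index = ndist / denom)
}

#' Haplotype census of every block for every group
#'
#' Vectorised application of the [census_block()] count over all blocks
#' and groups. With `counter = "segregating"` the per-block count is the
#' number of segregating SNP sites within the window instead of the
#' number of distinct haplotype strings (an alternative reading of
#' "number of polymorphisms"; not the default).
#'
#' @param x a `geno_matrix`
#' @param blocks table from [enumerate_blocks()]
#' @param groups named list of accession-id character vectors; defaults to
#'   the irrigated members of groups 1-3
#' @param counter `"haplotypes"` (default) or `"segregating"`
#' @param complete_case_denominator see [census_block()]
#' @return data frame with one row per block x group: `block_id`, `group`,
#'   `n_group`, `n_complete`, `n_distinct_haplotypes`, `diversity_index`,
#'   ordered by group then block
#' @export
census_all <- function(x, blocks, groups = NULL,
                       counter = c("haplotypes", "segregating"),
                       complete_case_denominator = FALSE) {
  counter <- match.arg(counter)
  if (is.null(groups)) {
    groups <- list(group1 = group_members(x, "group1"),
                   group2 = group_members(x, "group2"),
                   group3 = group_members(x, "group3"))
  }
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  window <- attr(blocks, "window") %||% 5L
  s_all <- window_strings(x, blocks)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    ids <- groups[[gi]]
    if (length(ids) == 0) stop("empty group: ", names(groups)[gi])
    rows <- .acc_rows(x, ids)
    s <- s_all[rows, , drop = FALSE]
    ncomp <- colSums(!is.na(s))
    if (counter == "haplotypes") {
      ndist <- vapply(seq_len(ncol(s)), function(j) {
        v <- s[, j]
        length(unique(v[!is.na(v)]))
      }, integer(1))
    } else {
      ndist <- vapply(seq_len(nrow(blocks)), function(j) {
        cols <- x$calls[rows, blocks$start_idx[j] + 0:(window - 1L),
                        drop = FALSE]
        sum(apply(cols, 2, function(col) {
          length(unique(col[!is.na(col)])) > 1
        }))
      }, integer(1))
    }
    denom <- if (complete_case_denominator) pmax(ncomp, 1L) else length(ids)
    out[[gi]] <- data.frame(
      block_id = blocks$block_id,
      group = names(groups)[gi],
      n_group = length(ids),
      n_complete = ncomp,
      n_distinct_haplotypes = ndist,
      diversity_index = ndist / denom,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expected mean window span for an evenly covered genome
#'
#' For `n_snps` markers spread over `genome_bp` of genome, a window of
#' `window` SNPs spans on average `window * genome_bp / n_snps` base
#' pairs; e.g. five-SNP windows on a 380-Mb genome with 3259 SNPs average
#' about 583 kb.
#'
#' @param genome_bp total genome length in bp
#' @param n_snps number of mapped SNPs
#' @param window window size in SNPs
#' @return expected span in kb
#' @export
expected_window_span_kb <- function(genome_bp, n_snps, window = 5) {
  window * (genome_bp / n_snps) / 1000
}
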