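#' Squared linkage-disequilibrium correlation for two haploid call vectors
#'
#' For inbred homozygous lines each accession contributes one haplotype,
#' so with `p` and `q` the allele-A frequencies at the two SNPs among
#' complete-case accessions, `x11` the joint A,A frequency and
#' `D = x11 - p*q`, the statistic is `D^2 / (p(1-p) q(1-q))` - the
#' squared correlation of the 0/1-coded vectors. Undefined (`NA`) when
#' either SNP is monomorphic among the complete cases or fewer than two
#' complete cases exist; invariant to allele relabelling and to the order
#' of its arguments.
#'
#' @param calls_i,calls_j character call vectors (`"A"`/`"B"`/`NA`) over
#'   the same accessions
#' @return squared correlation in `[0, 1]`, or `NA`
#' @export
delta_squared <- function(calls_i, calls_j) {
  stopifnot(length(calls_i) == length(calls_j))
  ok <- !is.na(calls_i) & !is.na(calls_j)
  if (sum(ok) < 2) return(NA_real_)
  a_i <- calls_i[ok] == "A"
  a_j <- calls_j[ok] == "A"
  p <- mean(a_i)
  q <- mean(a_j)
  den <- p * (1 - p) * q * (1 - q)
  if (den == 0) return(NA_real_)
  d <- mean(a_i & a_j) - p * q
  d * d / den
}

#' Delta-squared for all adjacent SNP pairs in a group
#'
#' "Adjacent" means consecutive in map order on the same chromosome;
#' pairs farther apart than `max_kb` are excluded.
#'
#' @param x a QC'd `geno_matrix`
#' @param group_ids accession ids forming the group
#' @param max_kb maximum pair distance in kb (default 2000)
#' @return data frame: `snp_i`, `snp_j`, `chromosome`, `distance_bp`,
#'   `n_complete`, `delta_sq`
#' @export
adjacent_ld <- function(x, group_ids, max_kb = 2000) {
  stopifnot(inherits(x, "geno_matrix"))
  if (length(group_ids) == 0) stop("empty group")
  rows <- .acc_rows(x, group_ids)
  s <- x$snps
  mapped <- which(!is.na(s$position_bp) & !is.na(s$chromosome))
  i <- mapped[-length(mapped)]
  j <- mapped[-1]
  same <- s$chromosome[i] == s$chromosome[j]
  i <- i[same]; j <- j[same]
  dist <- s$position_bp[j] - s$position_bp[i]
  keep <- dist > 0 & dist <= max_kb * 1000
  i <- i[keep]; j <- j[keep]; dist <- dist[keep]
  d2 <- numeric(length(i))
  ncomp <- integer(length(i))
  for (k in seq_along(i)) {
    ci <- x$calls[rows, i[k]]
    cj <- x$calls[rows, j[k]]
    ncomp[k] <- sum(!is.na(ci) & !is.na(cj))
    d2[k] <- delta_squared(ci, cj)
  }
  data.frame(snp_i = s$snp_id[i], snp_j = s$snp_id[j],
             chromosome = s$chromosome[i], distance_bp = dist,
             n_complete = ncomp, delta_sq = d2,
             stringsAsFactors = FALSE)
}

#' Binned LD profile of adjacent SNP pairs
#'
#' Bins adjacent-pair delta-squared values by distance into left-open,
#' right-closed 50-kb intervals anchored at 0 (so a 50,000-bp pair falls
#' in bin 1 and a 50,001-bp pair in bin 2), up to `max_kb`. By default the
#' bin mean is taken over pairs in "complete LD", `0 < delta^2 < 1`,
#' excluding exact 0s and exact 1s, whose counts are still reported; set
#' `complete_only = FALSE` to average over all defined values.
#'
#' @param x a QC'd `geno_matrix`
#' @param group_ids accession ids forming the group
#' @param bin_kb bin width in kb (default 50)
#' @param max_kb maximum distance in kb (default 2000)
#' @param complete_only restrict bin means to `0 < delta^2 < 1`
#' @return object of class `ld_profile`: data frame with one row per bin
#'   (`bin`, `lo_kb`, `hi_kb`, `n_pairs`, `n_defined`, `n_zero`, `n_one`,
#'   `n_complete_ld`, `mean_delta_sq`), with the per-pair table in
#'   attribute `"pairs"`
#' @export
ld_profile <- function(x, group_ids, bin_kb = 50, max_kb = 2000,
                       complete_only = TRUE) {
  pairs <- adjacent_ld(x, group_ids, max_kb = max_kb)
  n_bins <- ceiling(max_kb / bin_kb)
  if (nrow(pairs) == 0 || all(is.na(pairs$delta_sq))) {
    warning("no usable adjacent SNP pairs for this group")
  }
  bin <- ceiling(pairs$distance_bp / (bin_kb * 1000))
  prof <- data.frame(bin = seq_len(n_bins),
                     lo_kb = (seq_len(n_bins) - 1) * bin_kb,
                     hi_kb = seq_len(n_bins) * bin_kb)
  agg <- function(f) vapply(seq_len(n_bins), function(b) {
    f(pairs$delta_sq[bin == b])
  }, numeric(1))
  prof$n_pairs <- as.integer(agg(length))
  prof$n_defined <- as.integer(agg(function(v) sum(!is.na(v))))
  prof$n_zero <- as.integer(agg(function(v) sum(!is.na(v) & v == 0)))
  prof$n_one <- as.integer(agg(function(v) sum(!is.na(v) & v == 1)))
  prof$n_complete_ld <- as.integer(agg(function(v) sum(!is.na(v) & v > 0 & v < 1)))
  prof$mean_delta_sq <- agg(function(v) {
    v <- v[!is.na(v)]
    if (complete_only) v <- v[v > 0 & v < 1]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  attr(prof, "pairs") <- pairs
  attr(prof, "bin_kb") <- bin_kb
  attr(prof, "complete_only") <- complete_only
  class(prof) <- c("ld_profile", "data.frame")
  prof
}

#' Plot one or more LD profiles
#'
#' @param x an `ld_profile`
#' @param ... further `ld_profile` objects to overlay
#' @param labels legend labels, one per profile
#' @param col line colours
#' @return invisibly, `NULL`
#' @export
plot.ld_profile <- function(x, ..., labels = NULL, col = NULL) {
  profs <- c(list(x), list(...))
  profs <- Filter(function(p) inherits(p, "ld_profile"), profs)
  if (is.null(col)) col <- seq_along(profs)
  ylim <- range(unlist(lapply(profs, function(p) p$mean_delta_sq)), na.rm = TRUE)
  mid <- (x$lo_kb + x$hi_kb) / 2
  graphics::plot(mid, profs[[1]]$mean_delta_sq, type = "l", col = col[1],
                 ylim = ylim, xlab = "distance between adjacent SNPs (kb)",
                 ylab = expression(mean ~ Delta^2))
  if (length(profs) > 1) {
    for (k in 2:length(profs)) {
      graphics::lines(mid, profs[[k]]$mean_delta_sq, col = col[k])
    }
  }
  if (!is.null(labels)) {
    graphics::legend("topright", legend = labels, col = col, lty = 1, bty = "n")
  }
  invisible(NULL)
}
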