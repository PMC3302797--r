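mk_census <- function(ids, n, ncomp = 10L, ngroup = 10L, group = "g") {
  # a block with zero distinct haplotypes can only arise from zero
  # complete cases; keep hand fixtures consistent with that
  ncomp <- rep(ncomp, length.out = length(ids))
  data.frame(block_id = ids, group = group, n_group = ngroup,
             n_complete = ncomp, n_distinct_haplotypes = n,
             diversity_index = n / ngroup, stringsAsFactors = FALSE)
}

test_that("comparing a census with itself gives all ties and p near 1", {
  cen <- mk_census(1:20, sample(1:5, 20, replace = TRUE))
  cmp <- compare_groups(cen, cen)
  expect_identical(cmp$n_ties, 20L)
  expect_identical(cmp$n_higher_in_first, 0L)
  expect_gt(cmp$mannwhitney_p, 0.9)
})

test_that("fully separated indices give the exact enumerated rank-sum p", {
  a <- mk_census(1:3, c(9, 8, 7))
  b <- mk_census(1:3, c(1, 2, 3))
  cmp <- compare_groups(a, b)
  expect_identical(cmp$n_higher_in_first, 3L)
  # exact two-sided Mann-Whitney for complete separation at n = m = 3:
  # 2 / choose(6, 3) enumerated orderings
  expect_equal(cmp$mannwhitney_p, 2 / choose(6, 3))
  expect_error(compare_groups(a, mk_census(4:6, c(1, 2, 3))),
               "identical block sets")
})

test_that("bottleneck simulations show majority-higher phase-1 diversity", {
  sim <- small_sim(1)
  cen <- census_all(sim$panel, enumerate_blocks(sim$panel$snps))
  cg <- split(cen, cen$group)
  cmp <- compare_groups(cg$group1, cg$group2)
  expect_gt(cmp$n_higher_in_first, cmp$n_higher_in_second)
  expect_lt(cmp$mannwhitney_p, 0.05)
})

test_that("collapse flagging uses strict less-than on both later groups", {
  g1 <- mk_census(1:4, c(4, 4, 1, 0), ncomp = c(10L, 10L, 10L, 0L))
  g2 <- mk_census(1:4, c(1, 2, 0, 0), ncomp = c(10L, 10L, 0L, 0L), group = "g2")
  g3 <- mk_census(1:4, c(1, 1, 0, 0), ncomp = c(10L, 10L, 0L, 0L), group = "g3")
  fl <- flag_reduced_blocks(g1, g2, g3)
  expect_true(1 %in% fl)        # (4,1,1): both 1 < 2
  expect_false(2 %in% fl)       # (4,2,1): 2 is not < 2
  expect_false(3 %in% fl)       # (1,0,0): excluded, zero-count later groups
  expect_false(4 %in% fl)       # reference count 0 never flags

  # ratio limits: 0 flags nothing; 1 flags strictly-below blocks
  expect_identical(length(flag_reduced_blocks(g1, g2, g3, ratio = 0)), 0L)
  fl1 <- flag_reduced_blocks(g1, g2, g3, ratio = 1)
  expect_true(all(c(1, 2) %in% fl1))
})

test_that("zero-count exclusion is driven by complete-case availability", {
  g1 <- mk_census(1, 4)
  g2 <- mk_census(1, 1, group = "g2")
  g3 <- mk_census(1, 1, ncomp = 0L, group = "g3")   # all-missing group
  expect_identical(length(flag_reduced_blocks(g1, g2, g3)), 0L)
})

# brute-force run finder over the flag vector
oracle_regions <- function(blocks, flagged_ids, min_blocks = 2) {
  fl <- sort(intersect(blocks$block_id, flagged_ids))
  runs <- list()
  cur <- c()
  for (id in fl) {
    same_run <- length(cur) > 0 && id == cur[length(cur)] + 1 &&
      blocks$chromosome[blocks$block_id == id] ==
        blocks$chromosome[blocks$block_id == cur[length(cur)]]
    if (same_run) cur <- c(cur, id) else {
      if (length(cur)) runs[[length(runs) + 1]] <- cur
      cur <- id
    }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  runs[vapply(runs, length, integer(1)) >= min_blocks]
}

test_that("region merging matches a brute-force run finder", {
  set.seed(55)
  for (rep in 1:20) {
    counts <- sample(5:15, 3, replace = TRUE)
    snps <- data.frame(
      snp_id = sprintf("s%03d", seq_len(sum(counts))),
      chromosome = rep(1:3, counts),
      position_bp = unlist(lapply(counts, function(k) sort(sample.int(1e6, k)))),
      source_panel = "other", stringsAsFactors = FALSE
    )
    blocks <- enumerate_blocks(snps)
    flagged <- sample(blocks$block_id, size = rbinom(1, nrow(blocks), 0.4))
    regions <- merge_regions(blocks, flagged)
    runs <- oracle_regions(blocks, flagged)
    expect_identical(nrow(regions), length(runs))
    if (length(runs)) {
      expect_identical(regions$n_blocks,
                       as.integer(vapply(runs, length, integer(1))))
      expect_identical(regions$first_block_id,
                       as.integer(vapply(runs, min, numeric(1))))
    }
    # idempotence: regions cover every flagged block exactly once pre-filter
    all_runs <- oracle_regions(blocks, flagged, min_blocks = 1)
    expect_identical(sort(unlist(all_runs)), sort(intersect(blocks$block_id,
                                                            flagged)))
  }
})

test_that("regions report spans and kb lengths from first to last SNP", {
  snps <- data.frame(
    snp_id = sprintf("s%02d", 1:8), chromosome = 1L,
    position_bp = c(100000L, 110000L, 120000L, 140000L, 150000L,
                    162000L, 600000L, 700000L),
    source_panel = "other", stringsAsFactors = FALSE
  )
  blocks <- enumerate_blocks(snps)  # 4 windows
  regions <- merge_regions(blocks, c(1L, 2L))
  expect_identical(nrow(regions), 1L)
  expect_identical(regions$start_bp, 100000L)  # first SNP of first block
  expect_identical(regions$end_bp, 162000L)    # last SNP of last block
  expect_equal(regions$length_kb, 62)
  expect_identical(regions$n_blocks, 2L)

  # an isolated flagged window is dropped at the default minimum
  expect_identical(nrow(merge_regions(blocks, 4L)), 0L)
  expect_identical(nrow(merge_regions(blocks, 4L, min_blocks = 1)), 1L)
})

test_that("annotation overlap uses closed intervals on matching chromosomes", {
  regions <- data.frame(region_id = 1L, chromosome = 11L,
                        start_bp = 11600000L, end_bp = 14600000L,
                        n_blocks = 3L, length_kb = 3000,
                        first_block_id = 1L, last_block_id = 3L)
  ann <- data.frame(
    chromosome = c(11L, 11L, 5L),
    start_bp = c(12200000L, 11000000L, 12200000L),
    end_bp = c(14200000L, 11600000L, 14200000L),
    label = c("cen11", "touches_start", "wrong_chr"),
    kind = c("centromere", "qtl", "qtl"), stringsAsFactors = FALSE
  )
  out <- annotate_regions(regions, ann)
  lab <- strsplit(out$labels, ",")[[1]]
  expect_true("cen11" %in% lab)
  expect_true("touches_start" %in% lab)   # shares exactly one bp
  expect_false("wrong_chr" %in% lab)
  expect_identical(out$n_qtl, 1L)

  # empty annotation set leaves regions unchanged with zero counts
  out2 <- annotate_regions(regions, ann[0, ])
  expect_identical(out2$n_qtl, 0L)
  expect_identical(out2$labels, "")
})

test_that("flagged blocks concentrate in recombination-suppressed intervals", {
  in_cen <- out_cen <- n_in <- n_out <- 0
  for (s in 1:3) {
    sim <- small_sim(s)
    L <- sim$config$chromosome_length_bp
    blocks <- enumerate_blocks(sim$panel$snps)
    cen <- census_all(sim$panel, blocks)
    cg <- split(cen, cen$group)
    fl <- flag_reduced_blocks(cg$group1, cg$group2, cg$group3)
    mid <- (blocks$start_bp + blocks$end_bp) / 2
    inside <- mid >= 0.4 * L & mid <= 0.6 * L
    in_cen <- in_cen + sum(blocks$block_id[inside] %in% fl)
    out_cen <- out_cen + sum(blocks$block_id[!inside] %in% fl)
    n_in <- n_in + sum(inside)
    n_out <- n_out + sum(!inside)
  }
  expect_gt(in_cen / n_in, out_cen / n_out)
})
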