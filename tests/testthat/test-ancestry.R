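ped_df <- function(...) {
  rows <- list(...)
  p <- do.call(rbind, lapply(rows, function(r) {
    data.frame(child = r[1], parent1 = r[2], parent2 = r[3],
               recurrent_parent = if (length(r) > 3) r[4] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  class(p) <- c("pedigree_df", "data.frame")
  p
}

test_that("a single cross splits founder shares evenly", {
  ped <- ped_df(c("c1", "f1", "f2"))
  ff <- founder_frequencies(ped, "c1")
  expect_equal(ff$share[order(ff$founder)], c(0.5, 0.5))
  expect_equal(sum(ff$share), 1)
})

test_that("recurrent-parent edges are skipped in ancestor counting", {
  # c1 = f1 x f2; bc = backcross of c1 to recurrent f1
  ped <- ped_df(c("c1", "f1", "f2"), c("bc", "c1", "f1", "f1"))
  ff <- founder_frequencies(ped, "bc")
  # only the donor path is walked: f1 and f2 once each via c1
  expect_equal(ff$count[match(c("f1", "f2"), ff$founder)], c(1, 1))
  expect_equal(ff$share[match(c("f1", "f2"), ff$founder)], c(0.5, 0.5))
})

test_that("a founder reached along two paths counts twice under occurrence mode", {
  ped <- ped_df(c("c1", "f1", "f2"), c("c2", "f1", "f3"),
                c("c3", "c1", "c2"))
  ff <- founder_frequencies(ped, "c3")
  expect_equal(ff$count[ff$founder == "f1"], 2)
  expect_equal(ff$share[ff$founder == "f1"], 0.5)
  ffu <- founder_frequencies(ped, "c3", mode = "unique")
  expect_equal(ffu$share[ffu$founder == "f1"], 1 / 3)
})

test_that("pedigree cycles are detected and reported", {
  ped <- ped_df(c("a", "b", "x"), c("b", "c", "y"), c("c", "a", "z"))
  expect_error(founder_frequencies(ped, "a"), "cycle")
})

test_that("simulated bottleneck pedigrees concentrate founder ancestry", {
  sim <- default_sim()
  ped <- sim$truth$pedigree
  g2 <- intersect(group_members(sim$panel, "group2"), ped$child)
  ff2 <- founder_frequencies(ped, g2)
  expect_equal(sum(ff2$share), 1)
  # phase-1 material is its own ancestry: each accession contributes only
  # itself, so its top-11 share is 11 / 41; the bred phase-2 pool must be
  # at least as concentrated
  expect_gte(top_founder_share(ff2, 11), 11 / 41)
})

test_that("admixture classification is a strict threshold on the top component", {
  q <- rbind(a = c(0.9, 0.1, 0, 0),
             b = c(0.5, 0.3, 0.1, 0.1),
             c = c(0.8, 0.2, 0, 0))
  expect_identical(unname(classify_admixed(q)),
                   c(FALSE, TRUE, FALSE))  # 0.8 is not admixed (strict <)
})

test_that("identical groups share a letter and separated groups split", {
  q <- matrix(c(rep(0.6, 6), rep(0.4, 6)), ncol = 2,
              dimnames = list(paste0("a", 1:6), c("x", "y")))
  st <- group_component_stats(q, list(g1 = paste0("a", 1:3),
                                      g2 = paste0("a", 4:6)))
  expect_true(all(st$table$letters == "a"))

  # complete separation with heavy ties ({1,1,1} vs {0,0,0}): the
  # tie-corrected rank-sum approximation drops just below 0.05 (the exact
  # enumeration bound would be 2 / choose(6,3) = 0.1), so the two groups
  # earn distinct letters after correcting for the single comparison
  q2 <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1, 1, 1), ncol = 2,
               dimnames = list(paste0("a", 1:6), c("x", "y")))
  st2 <- group_component_stats(q2, list(g1 = paste0("a", 1:3),
                                        g2 = paste0("a", 4:6)))
  pref <- suppressWarnings(wilcox.test(c(1, 1, 1), c(0, 0, 0)))$p.value
  expect_equal(min(st2$pairwise$p_adjusted), pref)
  expect_identical(st2$table$letters[st2$table$component == "x"],
                   c("a", "b"))
  expect_equal(st2$table$mean[st2$table$component == "x"], c(1, 0))
  expect_equal(st2$table$se[st2$table$component == "x"], c(0, 0))
})

test_that("clearly separated n=4 groups earn distinct letters", {
  vals <- c(0.9, 0.85, 0.95, 0.88, 0.1, 0.15, 0.05, 0.12)
  q <- cbind(x = vals, y = 1 - vals)
  rownames(q) <- paste0("a", 1:8)
  st <- group_component_stats(q, list(hi = paste0("a", 1:4),
                                      lo = paste0("a", 5:8)))
  lx <- st$table$letters[st$table$component == "x"]
  expect_identical(lx, c("a", "b"))
})

test_that("four groups by four components give 16 cells and 6 tests per component", {
  set.seed(12)
  q <- matrix(runif(80), ncol = 4)
  q <- q / rowSums(q)
  rownames(q) <- paste0("a", 1:20)
  colnames(q) <- c("w", "e", "c", "n")
  groups <- split(rownames(q), rep(1:4, each = 5))
  names(groups) <- paste0("g", 1:4)
  st <- group_component_stats(q, groups)
  expect_identical(nrow(st$table), 16L)
  expect_identical(nrow(st$pairwise), as.integer(4 * choose(4, 2)))
  expect_true(all(nchar(st$table$letters) >= 1))
})

test_that("simple-matching distances satisfy their defining ratios", {
  calls <- rbind(a = c("A", "A", "B", "B", "A", "B", "A", "A", "B", "B"),
                 b = c("A", "A", "B", "B", "A", "B", "A", "A", "B", "B"),
                 c = c("B", "B", "A", "A", "B", "A", "B", "B", "A", "A"))
  x <- toy_matrix(calls)
  d <- simple_matching_distance(x)
  expect_equal(d["a", "b"], 0)     # identical
  expect_equal(d["a", "c"], 1)     # complementary at all 10 sites

  calls2 <- calls
  calls2["b", 1:2] <- c("B", "B")  # 8 matches of 10 comparable
  d2 <- simple_matching_distance(toy_matrix(calls2))
  expect_equal(d2["a", "b"], 0.2)
})

test_that("distance matrices are symmetric with zero diagonals", {
  set.seed(8)
  for (rep in 1:5) {
    x <- toy_matrix(random_calls(10, 30, miss = 0.2))
    d <- simple_matching_distance(x)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 10))
    expect_true(all(d >= 0 & d <= 1, na.rm = TRUE))
  }
})

test_that("PHYLIP export writes a parseable square matrix", {
  x <- toy_matrix(random_calls(4, 12, miss = 0))
  d <- simple_matching_distance(x)
  path <- withr::local_tempfile()
  write_phylip_dist(d, path)
  lines <- readLines(path)
  expect_identical(length(lines), 5L)
  expect_identical(as.integer(trimws(lines[1])), 4L)
  row1 <- as.numeric(strsplit(trimws(substring(lines[2], 11)), " +")[[1]])
  expect_equal(row1, unname(d[1, ]), tolerance = 1e-6)
})
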