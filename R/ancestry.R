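#' Founder (root-ancestor) frequencies from pedigree records
#'
#' Walks every pedigree path from each cultivar up to nodes with no
#' recorded parents, counting one occurrence per path (a founder reached
#' through two different crosses counts twice; `mode = "unique"` counts
#' each founder at most once per cultivar). Edges to a recurrent parent
#' are skipped, so in backcross breeding only the donor lineage of the
#' backcross contributes - the recurrent parent's subtree is excluded
#' from the ancestor count.
#'
#' @param pedigree a `pedigree_df` (see [read_pedigree()])
#' @param cultivars cultivar ids whose ancestries are pooled
#' @param mode `"occurrences"` (default) or `"unique"`
#' @return object of class `founder_freq`: data frame `founder`, `count`,
#'   `share`, sorted by decreasing share, with `total` attribute
#' @export
founder_frequencies <- function(pedigree, cultivars,
                                mode = c("occurrences", "unique")) {
  mode <- match.arg(mode)
  parents <- split(
    data.frame(p = c(pedigree$parent1, pedigree$parent2),
               rec = rep(pedigree$recurrent_parent, 2),
               stringsAsFactors = FALSE),
    rep(pedigree$child, 2)
  )
  memo <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())

  occ <- function(node) {
    if (!is.null(memo[[node]])) return(memo[[node]])
    if (!is.null(visiting[[node]])) {
      stop("pedigree cycle detected at: ", node)
    }
    pr <- parents[[node]]
    pr <- if (is.null(pr)) character() else pr$p[!is.na(pr$p) & (is.na(pr$rec) | pr$p != pr$rec)]
    if (length(pr) == 0) {
      res <- stats::setNames(1, node)
    } else {
      visiting[[node]] <- TRUE
      vecs <- lapply(pr, occ)
      rm(list = node, envir = visiting)
      nm <- unique(unlist(lapply(vecs, names)))
      res <- stats::setNames(numeric(length(nm)), nm)
      for (v in vecs) res[names(v)] <- res[names(v)] + v
    }
    memo[[node]] <- res
    res
  }

  missing <- setdiff(cultivars, c(pedigree$child, pedigree$parent1,
                                  pedigree$parent2))
  if (length(missing)) stop("cultivar not in pedigree: ", missing[1])

  total <- numeric(0)
  for (cv in cultivars) {
    v <- occ(cv)
    if (mode == "unique") v <- stats::setNames(rep(1, length(v)), names(v))
    nm <- union(names(total), names(v))
    new_total <- stats::setNames(numeric(length(nm)), nm)
    new_total[names(total)] <- total
    new_total[names(v)] <- new_total[names(v)] + v
    total <- new_total
  }
  if (sum(total) == 0) stop("no counted ancestor occurrences")
  out <- data.frame(founder = names(total), count = unname(total),
                    share = unname(total) / sum(total),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share, out$founder), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- sum(total)
  class(out) <- c("founder_freq", "data.frame")
  out
}

#' Summed share of the top-k founders
#'
#' @param ff a `founder_freq` table
#' @param k number of leading founders (default 11)
#' @return numeric scalar in `[0, 1]`
#' @export
top_founder_share <- function(ff, k = 11) {
  sum(utils::head(ff$share, k))
}

#' Flag admixed accessions from a Q-matrix
#'
#' An accession is admixed when no single ancestral component reaches the
#' threshold: `max(Q_row) < threshold` (strict, so a row with maximum
#' exactly 0.8 is not admixed).
#'
#' @param q Q-matrix (accessions x components), rows summing to 1
#' @param threshold single-ancestor majority threshold (default 0.8)
#' @return named logical vector, `TRUE` = admixed
#' @export
classify_admixed <- function(q, threshold = 0.8) {
  stopifnot(is.matrix(q))
  apply(q, 1, max) < threshold
}

#' Group-wise statistics of ancestral components
#'
#' For every ancestral component, computes each group's mean and standard
#' error (sd/sqrt(n)), all pairwise two-sided Mann-Whitney tests with a
#' per-component Bonferroni correction (p times the number of pairs,
#' capped at 1), and a compact letter display: groups are processed in
#' descending mean order and share a letter exactly when their adjusted p
#' is at or above `alpha`.
#'
#' @param q Q-matrix (accessions x components)
#' @param groups named list of accession-id character vectors (>= 2
#'   groups, each >= 2 accessions for a defined SE)
#' @param alpha significance level for the letter display (default 0.05)
#' @return object of class `component_stats`: list with `table` (rows =
#'   component x group: `component`, `group`, `n`, `mean`, `se`,
#'   `letters`) and `pairwise` (component, pair, raw and adjusted p)
#' @export
group_component_stats <- function(q, groups, alpha = 0.05) {
  stopifnot(is.matrix(q), length(groups) >= 2, !is.null(names(groups)))
  comps <- colnames(q) %||% paste0("C", seq_len(ncol(q)))
  gnames <- names(groups)
  rows <- lapply(groups, function(ids) {
    m <- match(ids, rownames(q))
    if (anyNA(m)) stop("accession not in Q-matrix: ", ids[is.na(m)][1])
    m
  })
  n_pairs <- choose(length(groups), 2)
  tab <- list()
  pw <- list()
  for (ci in seq_along(comps)) {
    vals <- lapply(rows, function(r) q[r, ci])
    mu <- vapply(vals, mean, numeric(1))
    se <- vapply(vals, function(v) {
      if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
    }, numeric(1))
    padj <- matrix(NA_real_, length(groups), length(groups),
                   dimnames = list(gnames, gnames))
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        praw <- suppressWarnings(
          stats::wilcox.test(vals[[i]], vals[[j]])$p.value
        )
        # identical constant samples: no evidence of any difference
        if (is.na(praw)) praw <- 1
        pa <- min(1, praw * n_pairs)
        padj[i, j] <- pa; padj[j, i] <- pa
        pw[[length(pw) + 1L]] <- data.frame(
          component = comps[ci], group_a = gnames[i], group_b = gnames[j],
          p_raw = praw, p_adjusted = pa, stringsAsFactors = FALSE)
      }
    }
    letters_vec <- .letter_display(mu, padj, alpha)
    tab[[ci]] <- data.frame(
      component = comps[ci], group = gnames,
      n = vapply(vals, length, integer(1)),
      mean = unname(mu), se = unname(se), letters = letters_vec,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, tab),
                 pairwise = do.call(rbind, pw),
                 alpha = alpha),
            class = "component_stats")
}

# compact letter display: groups share a letter iff adjusted p >= alpha
.letter_display <- function(means, padj, alpha) {
  gn <- names(means)
  ord <- order(-means)
  classes <- list()
  nonsig <- function(a, b) padj[a, b] >= alpha
  for (g in gn[ord]) {
    placed <- FALSE
    for (k in seq_along(classes)) {
      if (all(vapply(classes[[k]], function(m) nonsig(g, m), logical(1)))) {
        classes[[k]] <- c(classes[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- g
  }
  # ensure every non-significant pair shares at least one class
  for (i in seq_along(gn)) {
    for (j in seq_along(gn)) {
      if (j <= i) next
      if (nonsig(gn[i], gn[j]) &&
          !any(vapply(classes, function(cl) {
            all(c(gn[i], gn[j]) %in% cl)
          }, logical(1)))) {
        classes[[length(classes) + 1L]] <- c(gn[i], gn[j])
      }
    }
  }
  vapply(gn, function(g) {
    paste(sort(letters[which(vapply(classes, function(cl) g %in% cl,
                                    logical(1)))]), collapse = "")
  }, character(1))
}

#' @export
print.component_stats <- function(x, ...) {
  t <- x$table
  t$mean <- sprintf("%.3f", t$mean)
  t$se <- sprintf("%.3f", t$se)
  print(t, row.names = FALSE)
  cat(sprintf("(letters: groups sharing a letter do not differ at adjusted p < %.2f)\n",
              x$alpha))
  invisible(x)
}

#' Simple-matching distance matrix between accessions
#'
#' `d(x, y) = 1 - matches / comparable` over SNPs where both accessions
#' have non-missing calls; symmetric with a zero diagonal. Pairs with no
#' comparable SNP get `NA`.
#'
#' @param x a `geno_matrix`
#' @return numeric accession x accession distance matrix
#' @export
simple_matching_distance <- function(x) {
  stopifnot(inherits(x, "geno_matrix"), nrow(x$calls) >= 2)
  a <- x$calls == "A"; a[is.na(a)] <- FALSE
  b <- x$calls == "B"; b[is.na(b)] <- FALSE
  ok <- !is.na(x$calls)
  storage.mode(a) <- "double"
  storage.mode(b) <- "double"
  storage.mode(ok) <- "double"
  matches <- tcrossprod(a) + tcrossprod(b)
  comparable <- tcrossprod(ok)
  d <- 1 - matches / comparable
  d[comparable == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- list(rownames(x$calls), rownames(x$calls))
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d square distance matrix with row names
#' @param path output file
#' @return invisibly, `path`
#' @export
write_phylip_dist <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  nm <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(substr(nm[i], 1, 10), width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
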