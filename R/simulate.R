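#' Configuration for the breeding-program genotype simulator
#'
#' Defaults emulate the study design the package's analyses target: a
#' 12-chromosome, 3259-SNP array panel over a ~380-Mb genome; three
#' breeding-phase groups with 41/50/63 irrigated accessions (plus 22/1/0
#' non-irrigated landrace-type accessions, giving 63/51/63 in total);
#' four diverged ancestral pools behind the phase-1 landraces; improved
#' cultivars derived by pedigree-recorded crosses among a bottlenecked
#' founder subset; and novel haplotype polymorphisms accruing along
#' breeding lineages at about three per year over registration years
#' 1931-2005.
#'
#' @param n_chromosomes number of chromosomes (default 12)
#' @param snps_per_chromosome integer vector, one count per chromosome
#'   (default: 3259 split as evenly as possible); every chromosome needs
#'   at least 5 SNPs
#' @param chromosome_length_bp length of each chromosome (default
#'   31.7 Mb, so the genome is ~380 Mb)
#' @param n_ancestral_pools number of diverged ancestral allele-frequency
#'   pools (default 4: western, eastern, classic, non_irrigated)
#' @param pool_divergence Fst-like divergence of pool allele frequencies
#'   from the common ancestral frequency, in (0, 1) (default 0.25)
#' @param group_sizes named integer vector: irrigated accessions per
#'   breeding-phase group (default `c(group1 = 41, group2 = 50,
#'   group3 = 63)`)
#' @param non_irrigated_sizes non-irrigated accessions per group (default
#'   `c(22, 1, 0)`; the third entry must be 0)
#' @param founder_counts_per_phase length-2 integer: how many phase-1
#'   accessions found phase 2, and how many phase-2 cultivars found
#'   phase 3 (the bottleneck severity; default `c(10, 10)`)
#' @param crossovers_per_chromosome Poisson mean of crossovers per
#'   chromosome per cross (default 1)
#' @param novel_accrual_rate expected new haplotype-block polymorphisms
#'   per year of breeding (default 3); realised as SNP mutations at rate
#'   `novel_accrual_rate / window` per lineage-year, each perturbing
#'   `window` blocks
#' @param window haplotype-window size in SNPs (default 5)
#' @param year_range registration-year span of improved cultivars
#'   (default `c(1931, 2005)`)
#' @param year_split last phase-2 registration year (default 1974)
#' @param missing_rate,het_rate per-call corruption probabilities applied
#'   last (defaults 0.01 and 0.005; heterozygous calls in inbred material
#'   are treated as missing, so both end up as missing with separate
#'   bookkeeping)
#' @param backcross_prob probability that a cross is a recurrent-parent
#'   backcross (default 0.2)
#' @param centromere_fraction central fraction of each chromosome with
#'   suppressed recombination (default 0.2)
#' @param centromere_factor crossover retention probability inside the
#'   centromeric interval (default 0.1)
#' @param reserved_fraction fraction of SNPs kept monomorphic in phase 1
#'   as targets for novel mutations (default 0.15)
#' @param seed integer RNG seed, or `NULL` to use the current RNG state
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 12L,
                       snps_per_chromosome = NULL,
                       chromosome_length_bp = 31.7e6,
                       n_ancestral_pools = 4L,
                       pool_divergence = 0.25,
                       group_sizes = c(group1 = 41L, group2 = 50L, group3 = 63L),
                       non_irrigated_sizes = c(22L, 1L, 0L),
                       founder_counts_per_phase = c(10L, 10L),
                       crossovers_per_chromosome = 1,
                       novel_accrual_rate = 3,
                       window = 5L,
                       year_range = c(1931L, 2005L),
                       year_split = 1974L,
                       missing_rate = 0.01,
                       het_rate = 0.005,
                       backcross_prob = 0.2,
                       centromere_fraction = 0.2,
                       centromere_factor = 0.1,
                       reserved_fraction = 0.15,
                       seed = NULL) {
  if (is.null(snps_per_chromosome)) {
    snps_per_chromosome <- .even_split(3259L, n_chromosomes)
  }
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length_bp = chromosome_length_bp,
    n_ancestral_pools = as.integer(n_ancestral_pools),
    pool_divergence = pool_divergence,
    group_sizes = group_sizes,
    non_irrigated_sizes = as.integer(non_irrigated_sizes),
    founder_counts_per_phase = as.integer(founder_counts_per_phase),
    crossovers_per_chromosome = crossovers_per_chromosome,
    novel_accrual_rate = novel_accrual_rate,
    window = as.integer(window),
    year_range = as.integer(year_range),
    year_split = as.integer(year_split),
    missing_rate = missing_rate,
    het_rate = het_rate,
    backcross_prob = backcross_prob,
    centromere_fraction = centromere_fraction,
    centromere_factor = centromere_factor,
    reserved_fraction = reserved_fraction,
    seed = seed
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.even_split <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  as.integer(c(rep(base + 1L, extra), rep(base, n - extra)))
}

.validate_sim_config <- function(cfg) {
  if (length(cfg$snps_per_chromosome) != cfg$n_chromosomes) {
    stop("snps_per_chromosome must have one entry per chromosome")
  }
  if (any(cfg$snps_per_chromosome < 1)) {
    stop("every chromosome needs at least 1 SNP")
  }
  if (all(cfg$snps_per_chromosome < cfg$window)) {
    stop("at least one chromosome needs >= ", cfg$window,
         " SNPs to form a haplotype window")
  }
  probs <- c(cfg$missing_rate, cfg$het_rate, cfg$backcross_prob,
             cfg$centromere_factor, cfg$reserved_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$pool_divergence <= 0 || cfg$pool_divergence >= 1) {
    stop("pool_divergence must lie in (0, 1)")
  }
  if (length(cfg$group_sizes) != 3 || any(cfg$group_sizes < 1)) {
    stop("group_sizes must be 3 positive integers")
  }
  if (length(cfg$non_irrigated_sizes) != 3 || any(cfg$non_irrigated_sizes < 0)) {
    stop("non_irrigated_sizes must be 3 non-negative integers")
  }
  if (cfg$non_irrigated_sizes[3] > 0) {
    stop("group 3 admits no non-irrigated accessions")
  }
  if (length(cfg$founder_counts_per_phase) != 2 ||
      any(cfg$founder_counts_per_phase < 2)) {
    stop("founder_counts_per_phase must be 2 integers >= 2")
  }
  if (cfg$founder_counts_per_phase[1] > cfg$group_sizes[1] ||
      cfg$founder_counts_per_phase[2] > cfg$group_sizes[2]) {
    stop("founder counts cannot exceed the source group size")
  }
  if (cfg$novel_accrual_rate < 0) stop("novel_accrual_rate must be >= 0")
  if (cfg$year_range[1] >= cfg$year_range[2] ||
      cfg$year_split < cfg$year_range[1] || cfg$year_split >= cfg$year_range[2]) {
    stop("need year_range[1] <= year_split < year_range[2]")
  }
  invisible(cfg)
}

# one cross: child haploid genome as a recombinant mosaic of two parents
.cross_genomes <- function(g1, g2, snp_chr, snp_pos, cfg) {
  child <- g1
  L <- cfg$chromosome_length_bp
  cen_lo <- L * (0.5 - cfg$centromere_fraction / 2)
  cen_hi <- L * (0.5 + cfg$centromere_fraction / 2)
  for (chr in seq_len(cfg$n_chromosomes)) {
    idx <- which(snp_chr == chr)
    if (length(idx) == 0) next
    nx <- stats::rpois(1, cfg$crossovers_per_chromosome)
    bp <- sort(stats::runif(nx, 0, L))
    if (length(bp)) {
      in_cen <- bp >= cen_lo & bp <= cen_hi
      keep <- !in_cen | stats::runif(length(bp)) < cfg$centromere_factor
      bp <- bp[keep]
    }
    src <- (sample.int(2L, 1L) +
              findInterval(snp_pos[idx], bp)) %% 2L  # 0 -> g1, 1 -> g2
    child[idx[src == 1L]] <- g2[idx[src == 1L]]
  }
  child
}

#' Simulate a breeding-program genotype panel with recorded truth
#'
#' Phase-1 accessions are drawn from diverged ancestral allele-frequency
#' pools with per-accession admixture proportions. Improved (phase-2/3)
#' cultivars descend from a bottlenecked founder subset through
#' pedigree-recorded crosses (including recurrent-parent backcrosses)
#' with Poisson crossovers per chromosome and a recombination-suppressed
#' centromeric interval. Novel mutations are injected along breeding
#' lineages as a Poisson process in lineage-years at SNPs kept
#' monomorphic among phase-1 accessions, so that the expected
#' per-cultivar count of novel haplotype-block polymorphisms grows
#' linearly in registration year at `novel_accrual_rate`. Missing and
#' residual-heterozygote noise is applied last. Identical configuration
#' and seed reproduce the output exactly.
#'
#' @param config a [sim_config()]
#' @return object of class `hap_sim`: list with
#'   \describe{
#'     \item{panel}{the simulated [geno_matrix()]}
#'     \item{truth}{list: `qmatrix` (true ancestry proportions),
#'       `pedigree` (a `pedigree_df` of the simulated crosses),
#'       `novel_snps` (data frame `snp_id`, `year`, `accession` of
#'       injected mutations), `block_census` (pre-noise per-group distinct
#'       haplotype counts), `reserved_snp_ids`, `n_missing_applied`,
#'       `n_het_applied`}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  ## --- SNP map -------------------------------------------------------
  n_snp <- sum(cfg$snps_per_chromosome)
  snp_chr <- rep(seq_len(cfg$n_chromosomes), cfg$snps_per_chromosome)
  snp_pos <- unlist(lapply(seq_len(cfg$n_chromosomes), function(chr) {
    sort(sample.int(cfg$chromosome_length_bp, cfg$snps_per_chromosome[chr]))
  }))
  snp_id <- sprintf("c%02d_s%04d", snp_chr,
                    unlist(lapply(cfg$snps_per_chromosome, seq_len)))
  panel_src <- sample(c("koshihikari", "eiko", "rikuu132"), n_snp,
                      replace = TRUE, prob = c(2093, 493, 673))
  snps <- data.frame(snp_id = snp_id, chromosome = snp_chr,
                     position_bp = snp_pos, source_panel = panel_src,
                     stringsAsFactors = FALSE)

  ## --- ancestral pools ----------------------------------------------
  K <- cfg$n_ancestral_pools
  Fst <- cfg$pool_divergence
  p0 <- stats::runif(n_snp, 0.1, 0.9)  # ancestral freq of allele "B"
  pool_freq <- t(vapply(seq_len(K), function(k) {
    stats::rbeta(n_snp, p0 * (1 - Fst) / Fst, (1 - p0) * (1 - Fst) / Fst)
  }, numeric(n_snp)))
  reserved <- sort(sample.int(n_snp, round(cfg$reserved_fraction * n_snp)))
  pool_freq[, reserved] <- 0  # monomorphic "A" everywhere in phase 1

  pool_names <- c("western", "eastern", "classic", "non_irrigated",
                  paste0("pool", seq_len(max(0, K - 4)) + 4))[seq_len(K)]
  irr_pools <- seq_len(max(1, K - 1))
  nonirr_pool <- K

  ## --- accessions ----------------------------------------------------
  gs <- cfg$group_sizes
  nis <- cfg$non_irrigated_sizes
  ids <- c(
    sprintf("G1_IRR_%03d", seq_len(gs[1])),
    if (nis[1]) sprintf("G1_NIR_%03d", seq_len(nis[1])),
    sprintf("G2_IRR_%03d", seq_len(gs[2])),
    if (nis[2]) sprintf("G2_NIR_%03d", seq_len(nis[2])),
    sprintf("G3_IRR_%03d", seq_len(gs[3]))
  )
  grp <- c(rep("group1", gs[1] + nis[1]), rep("group2", gs[2] + nis[2]),
           rep("group3", gs[3]))
  regime <- c(rep("irrigated", gs[1]), rep("non_irrigated", nis[1]),
              rep("irrigated", gs[2]), rep("non_irrigated", nis[2]),
              rep("irrigated", gs[3]))
  n_acc <- length(ids)

  y0 <- cfg$year_range[1]
  years <- rep(NA_integer_, n_acc)
  is_g2i <- grp == "group2" & regime == "irrigated"
  is_g3i <- grp == "group3"
  years[is_g2i] <- sort(sample(seq(y0, cfg$year_split), gs[2], replace = TRUE))
  if (nis[2]) {
    years[grp == "group2" & regime == "non_irrigated"] <-
      sample(seq(y0, cfg$year_split), nis[2], replace = TRUE)
  }
  years[is_g3i] <- sort(sample(seq(cfg$year_split + 1L, cfg$year_range[2]),
                               gs[3], replace = TRUE))

  accs <- data.frame(accession_id = ids, group = grp, water_regime = regime,
                     registration_year = years, region = NA_character_,
                     stringsAsFactors = FALSE)

  ## --- phase-1 genomes (pool draws with admixture) -------------------
  calls <- matrix(NA_character_, n_acc, n_snp, dimnames = list(ids, snp_id))
  qmat <- matrix(0, n_acc, K, dimnames = list(ids, pool_names))
  phase1 <- which(grp == "group1" | (grp == "group2" & regime == "non_irrigated"))
  g1_irr_pool_prob <- c(0.3, 0.05, 0.65, rep(0, K - 3))[seq_len(K)]
  for (i in phase1) {
    main <- if (regime[i] == "non_irrigated") nonirr_pool else
      sample(irr_pools, 1, prob = g1_irr_pool_prob[irr_pools])
    alpha <- rep(0.4, K)
    alpha[main] <- 6
    gdraw <- stats::rgamma(K, alpha)
    qmat[i, ] <- gdraw / sum(gdraw)
    z <- sample.int(K, n_snp, replace = TRUE, prob = qmat[i, ])
    calls[i, ] <- ifelse(stats::runif(n_snp) < pool_freq[cbind(z, seq_len(n_snp))],
                         "B", "A")
  }

  ## --- improved cultivars: crosses + novel mutations -----------------
  year_of <- stats::setNames(rep(y0, n_acc), ids)
  year_of[!is.na(years)] <- years[!is.na(years)]
  # novel_accrual_rate is the expected OBSERVED accrual of novel
  # haplotype-block polymorphisms per lineage-year; convert it to a
  # per-SNP mutation intensity by the analytic observable fraction: a
  # random SNP sits in sum(n_c - w + 1) * w / n_snp windows (< w near
  # chromosome ends), and a window is counted only when all w calls
  # survive the missing/het corruption
  windows_per_snp <- sum(pmax(0L, cfg$snps_per_chromosome - cfg$window + 1L)) *
    cfg$window / n_snp
  m_eff <- cfg$missing_rate + (1 - cfg$missing_rate) * cfg$het_rate
  mu_snp <- cfg$novel_accrual_rate / (windows_per_snp * (1 - m_eff)^cfg$window)
  ped <- list()
  novel <- list()
  reserved_unused <- reserved
  pick <- function(v, n) v[sample.int(length(v), n)]

  g1_irr_ids <- ids[grp == "group1" & regime == "irrigated"]
  founders2 <- pick(g1_irr_ids, cfg$founder_counts_per_phase[1])
  g2_ids_ordered <- ids[is_g2i][order(years[is_g2i])]
  g3_ids_ordered <- ids[is_g3i][order(years[is_g3i])]

  breed_one <- function(child, allowed) {
    t_child <- year_of[[child]]
    backcross <- length(allowed) >= 2 &&
      stats::runif(1) < cfg$backcross_prob
    pr <- pick(allowed, 2)
    if (backcross) {
      donor <- pr[1]; rec <- pr[2]
      f1 <- .cross_genomes(calls[donor, ], calls[rec, ], snp_chr, snp_pos, cfg)
      g <- .cross_genomes(f1, calls[rec, ], snp_chr, snp_pos, cfg)
      qmat[child, ] <<- 0.25 * qmat[donor, ] + 0.75 * qmat[rec, ]
      ped[[length(ped) + 1L]] <<- data.frame(
        child = child, parent1 = donor, parent2 = rec,
        recurrent_parent = rec, stringsAsFactors = FALSE)
    } else {
      g <- .cross_genomes(calls[pr[1], ], calls[pr[2], ], snp_chr, snp_pos, cfg)
      qmat[child, ] <<- (qmat[pr[1], ] + qmat[pr[2], ]) / 2
      ped[[length(ped) + 1L]] <<- data.frame(
        child = child, parent1 = pr[1], parent2 = pr[2],
        recurrent_parent = NA_character_, stringsAsFactors = FALSE)
    }
    dt <- max(0, t_child - mean(year_of[pr]))
    n_mut <- stats::rpois(1, mu_snp * dt)
    if (n_mut > 0) {
      n_new <- min(n_mut, length(reserved_unused))
      targets <- integer(0)
      if (n_new > 0) {
        targets <- pick(reserved_unused, n_new)
        reserved_unused <<- setdiff(reserved_unused, targets)
      }
      if (n_mut > n_new) {
        # recurrent mutation once fresh targets run out: a mutation by
        # definition changes an allele, so only sites still wild-type in
        # this lineage are eligible
        avail <- setdiff(reserved[g[reserved] == "A"], targets)
        targets <- c(targets, pick(avail, min(n_mut - n_new, length(avail))))
      }
      if (length(targets)) {
        g[targets] <- "B"
        novel[[length(novel) + 1L]] <<- data.frame(
          snp_id = snp_id[targets], year = t_child, accession = child,
          stringsAsFactors = FALSE)
      }
    }
    calls[child, ] <<- g
  }

  made <- character(0)
  for (child in g2_ids_ordered) {
    breed_one(child, c(founders2, made))
    made <- c(made, child)
  }
  founders3 <- pick(g2_ids_ordered, cfg$founder_counts_per_phase[2])
  made <- character(0)
  for (child in g3_ids_ordered) {
    breed_one(child, c(founders3, made))
    made <- c(made, child)
  }

  pedigree <- if (length(ped)) do.call(rbind, ped) else
    data.frame(child = character(), parent1 = character(),
               parent2 = character(), recurrent_parent = character(),
               stringsAsFactors = FALSE)
  class(pedigree) <- c("pedigree_df", "data.frame")
  novel_snps <- if (length(novel)) do.call(rbind, novel) else
    data.frame(snp_id = character(), year = integer(),
               accession = character(), stringsAsFactors = FALSE)

  ## --- pre-noise truth census ---------------------------------------
  clean <- geno_matrix(calls, snps, accs)
  blocks <- enumerate_blocks(clean$snps, window = cfg$window)
  block_census <- census_all(clean, blocks)

  ## --- corruption noise ---------------------------------------------
  # clean's columns are position-sorted; apply noise there
  cc <- clean$calls
  drop_missing <- matrix(stats::runif(length(cc)) < cfg$missing_rate,
                         nrow(cc), ncol(cc))
  drop_het <- matrix(stats::runif(length(cc)) < cfg$het_rate,
                     nrow(cc), ncol(cc)) & !drop_missing
  n_missing <- sum(drop_missing & !is.na(cc))
  n_het <- sum(drop_het & !is.na(cc))
  cc[drop_missing | drop_het] <- NA
  panel <- geno_matrix(cc, clean$snps, clean$accessions)

  structure(
    list(panel = panel,
         truth = list(qmatrix = qmat,
                      pedigree = pedigree,
                      novel_snps = novel_snps,
                      block_census = block_census,
                      reserved_snp_ids = snp_id[reserved],
                      n_missing_applied = n_missing,
                      n_het_applied = n_het),
         config = cfg),
    class = "hap_sim"
  )
}

#' @export
print.hap_sim <- function(x, ...) {
  cat("simulated breeding-program panel\n")
  print(x$panel)
  cat("  injected novel mutations:", nrow(x$truth$novel_snps),
      "| pedigree records:", nrow(x$truth$pedigree), "\n")
  invisible(x)
}

#' Write a small fixture suite for tests and documentation
#'
#' Simulates a toy two-chromosome panel (the second chromosome carries
#' only 4 SNPs, so it yields no five-SNP window) and writes every
#' external format the package reads: genotype/SNP/accession TSVs, a
#' pedigree TSV, a Q-matrix TSV, an annotation BED (with label and kind
#' columns), and a truth JSON.
#'
#' @param out_dir output directory (created if needed)
#' @param seed RNG seed (default 20260921)
#' @return invisibly, named character vector of file paths
#' @export
emit_fixture_suite <- function(out_dir, seed = 20260921) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- sim_config(
    n_chromosomes = 2L, snps_per_chromosome = c(9L, 4L),
    chromosome_length_bp = 2e6, group_sizes = c(group1 = 5L, group2 = 4L,
                                                group3 = 4L),
    non_irrigated_sizes = c(2L, 0L, 0L), founder_counts_per_phase = c(3L, 3L),
    novel_accrual_rate = 2, missing_rate = 0.02, het_rate = 0.01,
    seed = seed
  )
  sim <- simulate_panel(cfg)
  paths <- write_genotype_table(sim$panel, out_dir, prefix = "toy")

  ppath <- file.path(out_dir, "toy_pedigree.tsv")
  utils::write.table(sim$truth$pedigree, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")

  qpath <- file.path(out_dir, "toy_qmatrix.tsv")
  qdf <- data.frame(accession_id = rownames(sim$truth$qmatrix),
                    sim$truth$qmatrix, check.names = FALSE)
  utils::write.table(qdf, qpath, sep = "\t", quote = FALSE, row.names = FALSE)

  bpath <- file.path(out_dir, "toy_annotations.bed")
  L <- cfg$chromosome_length_bp
  ann <- data.frame(
    chromosome = c(1L, 1L, 2L),
    start_bp = c(round(L * 0.4) + 1L, 1000L, 500L),
    end_bp = c(round(L * 0.6), 250000L, 200000L),
    label = c("cen1", "qtl_yield1", "qtl_quality2")
  )
  writeLines(sprintf("chr%d\t%d\t%d\t%s\t%s", ann$chromosome,
                     ann$start_bp - 1L, ann$end_bp, ann$label,
                     c("centromere", "qtl", "qtl")), bpath)

  jpath <- file.path(out_dir, "toy_truth.json")
  jsonlite::write_json(
    list(novel_snps = sim$truth$novel_snps,
         n_missing_applied = sim$truth$n_missing_applied,
         n_het_applied = sim$truth$n_het_applied,
         seed = seed),
    jpath, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, pedigree = ppath, qmatrix = qpath,
              annotations = bpath, truth = jpath))
}
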