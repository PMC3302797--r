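# in-code fixture builders and a per-run simulation cache

# build a geno_matrix from a character matrix of A/B/NA calls
toy_matrix <- function(calls, chromosome = NULL, position = NULL,
                       group = NULL, regime = NULL, year = NULL) {
  n_acc <- nrow(calls)
  n_snp <- ncol(calls)
  if (is.null(chromosome)) chromosome <- rep(1L, n_snp)
  if (is.null(position)) {
    position <- ave(seq_len(n_snp), chromosome, FUN = seq_along) * 1000L
  }
  if (is.null(group)) group <- rep("group1", n_acc)
  if (is.null(regime)) regime <- rep("irrigated", n_acc)
  if (is.null(year)) year <- rep(NA_integer_, n_acc)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("acc%03d", seq_len(n_acc))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("s%03d", seq_len(n_snp))
  }
  geno_matrix(
    calls,
    data.frame(snp_id = colnames(calls), chromosome = chromosome,
               position_bp = position, source_panel = "other",
               stringsAsFactors = FALSE),
    data.frame(accession_id = rownames(calls), group = group,
               water_regime = regime, registration_year = year,
               region = NA_character_, stringsAsFactors = FALSE)
  )
}

# simulations are reused across test files within one run
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- simulate_panel(cfg)
  .sim_cache[[key]]
}

default_sim <- function(seed = 101) {
  cached_sim(paste0("default", seed), sim_config(seed = seed))
}

# reduced panel: 3 chromosomes x 72 SNPs (204 five-SNP blocks), strong
# founder bottleneck, no non-irrigated accessions
small_bottleneck_config <- function(seed, ...) {
  sim_config(n_chromosomes = 3L, snps_per_chromosome = rep(72L, 3),
             chromosome_length_bp = 25e6,
             group_sizes = c(group1 = 20L, group2 = 20L, group3 = 20L),
             non_irrigated_sizes = c(0L, 0L, 0L),
             founder_counts_per_phase = c(4L, 4L),
             seed = seed, ...)
}

small_sim <- function(seed) {
  cached_sim(paste0("small", seed), small_bottleneck_config(seed))
}

# random A/B/NA call matrix
random_calls <- function(n_acc, n_snp, miss = 0.1) {
  m <- matrix(sample(c("A", "B"), n_acc * n_snp, replace = TRUE), n_acc, n_snp)
  m[matrix(runif(n_acc * n_snp) < miss, n_acc, n_snp)] <- NA
  m
}
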