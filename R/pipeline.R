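#' Validate and normalise a pipeline run configuration
#'
#' Accepts a YAML file path or a plain list. Unknown keys and invalid
#' values are reported exhaustively in one error. Missing keys receive
#' the method's standard defaults: five-SNP windows, 0.5 QC missing
#' fraction, 0.02 QC allele frequency, 0.5 diversity-collapse ratio with
#' a 2-block minimum region, 50-kb LD bins to 2000 kb, group-1 novelty
#' reference, and a 0.8 admixture threshold.
#'
#' @param config list, or path to a YAML file
#' @return normalised list of class `run_config`
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("simulation", "inputs", "qc", "window", "scan", "ld", "novel",
             "admixture_threshold", "annotations", "qmatrix", "pedigree",
             "out_dir", "seed", "skip")
  errs <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulation) || !has_inputs
  if (has_inputs) {
    req <- c("genotypes", "snp_meta", "accession_meta")
    miss <- setdiff(req, names(config$inputs))
    if (length(miss)) {
      errs <- c(errs, paste0("inputs missing: ", paste(miss, collapse = ", ")))
    }
  }
  defaults <- list(
    qc = list(max_missing_fraction = 0.5, min_allele_freq = 0.02),
    window = 5L,
    scan = list(ratio = 0.5, min_blocks = 2L),
    ld = list(bin_kb = 50, max_kb = 2000),
    novel = list(reference_group = "group1"),
    admixture_threshold = 0.8,
    out_dir = NULL, seed = NULL, skip = character(0)
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]])) {
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- defaults[[k]][[kk]]
      }
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(bad)) {
        errs <- c(errs, paste0("unknown key(s) under '", k, "': ",
                               paste(bad, collapse = ", ")))
      }
    }
  }
  if (!is.numeric(config$scan$ratio) || config$scan$ratio <= 0 ||
      config$scan$ratio > 1) {
    errs <- c(errs, "scan$ratio must lie in (0, 1]")
  }
  if (!is.numeric(config$window) || config$window < 2) {
    errs <- c(errs, "window must be an integer >= 2")
  }
  if (!is.numeric(config$qc$max_missing_fraction) ||
      config$qc$max_missing_fraction < 0 || config$qc$max_missing_fraction > 1) {
    errs <- c(errs, "qc$max_missing_fraction must lie in [0, 1]")
  }
  if (!is.numeric(config$qc$min_allele_freq) ||
      config$qc$min_allele_freq < 0 || config$qc$min_allele_freq >= 0.5) {
    errs <- c(errs, "qc$min_allele_freq must lie in [0, 0.5)")
  }
  if (!is.numeric(config$ld$bin_kb) || config$ld$bin_kb <= 0 ||
      !is.numeric(config$ld$max_kb) || config$ld$max_kb < config$ld$bin_kb) {
    errs <- c(errs, "ld bins need 0 < bin_kb <= max_kb")
  }
  if (!is.numeric(config$admixture_threshold) ||
      config$admixture_threshold <= 0 || config$admixture_threshold > 1) {
    errs <- c(errs, "admixture_threshold must lie in (0, 1]")
  }
  bad_skip <- setdiff(config$skip,
                      c("qc", "blocks", "scan", "ld", "novel", "ancestry"))
  if (length(bad_skip)) {
    errs <- c(errs, paste0("unknown skip stage(s): ",
                           paste(bad_skip, collapse = ", ")))
  }
  if (has_sim && !is.null(config$simulation) &&
      !inherits(config$simulation, "sim_config")) {
    cfg_try <- try(do.call(sim_config, config$simulation), silent = TRUE)
    if (inherits(cfg_try, "try-error")) {
      errs <- c(errs, paste0("invalid simulation config: ",
                             attr(cfg_try, "condition")$message))
    } else {
      config$simulation <- cfg_try
    }
  }
  if (length(errs)) {
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  config$window <- as.integer(config$window)
  class(config) <- c("run_config", "list")
  config
}

#' Run the full haplotype-dynamics pipeline
#'
#' Executes simulate/load -> QC -> block census -> diversity scan -> LD
#' profiles -> novel polymorphisms -> ancestry in dependency order,
#' writing per-stage CSV/BED/JSON files when `out_dir` is set, plus a
#' summary. Identical configuration and seed give an identical bundle.
#'
#' @param config a list or YAML path accepted by [validate_config()]
#' @return object of class `hap_run`: list of stage results plus
#'   `summary` (named list of headline numbers)
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  skip <- cfg$skip
  res <- list(config = cfg)

  ## stage: acquire panel
  if (!is.null(cfg$inputs)) {
    panel <- read_genotype_table(cfg$inputs$genotypes, cfg$inputs$snp_meta,
                                 cfg$inputs$accession_meta)
    truth <- NULL
  } else {
    sim_cfg <- cfg$simulation %||% sim_config(seed = cfg$seed)
    if (!is.null(cfg$seed)) sim_cfg$seed <- cfg$seed
    sim <- simulate_panel(sim_cfg)
    panel <- sim$panel
    truth <- sim$truth
    res$sim <- sim
  }
  summary <- list(n_accessions = nrow(panel$calls),
                  n_snps_input = ncol(panel$calls))

  ## stage: qc
  if (!("qc" %in% skip)) {
    qc <- filter_informative(panel, cfg$qc$max_missing_fraction,
                             cfg$qc$min_allele_freq)
    panel <- qc$panel
    res$qc_report <- qc$report
    emit(qc$report$dispositions, "qc_dispositions")
    summary$n_informative <- qc$report$n_informative
  }

  groups <- list(group1 = group_members(panel, "group1"),
                 group2 = group_members(panel, "group2"),
                 group3 = group_members(panel, "group3"))

  ## stage: blocks
  blocks <- census <- NULL
  if (!("blocks" %in% skip)) {
    blocks <- enumerate_blocks(panel$snps, window = cfg$window)
    census <- census_all(panel, blocks, groups)
    res$blocks <- blocks
    res$census <- census
    emit(blocks[, setdiff(names(blocks), "start_idx")], "blocks")
    emit(census, "block_census")
    summary$n_blocks <- nrow(blocks)
  }

  ## stage: scan
  if (!("scan" %in% skip) && !is.null(census)) {
    cg <- split(census, census$group)
    comp12 <- compare_groups(cg$group1, cg$group2)
    comp23 <- compare_groups(cg$group2, cg$group3)
    flagged <- flag_reduced_blocks(cg$group1, cg$group2, cg$group3,
                                   ratio = cfg$scan$ratio)
    regions <- merge_regions(blocks, flagged, min_blocks = cfg$scan$min_blocks)
    if (!is.null(cfg$annotations)) {
      regions <- annotate_regions(regions, read_annotations(cfg$annotations))
    }
    res$comparisons <- list(g1_vs_g2 = comp12, g2_vs_g3 = comp23)
    res$flagged_blocks <- flagged
    res$regions <- regions
    emit(regions, "reduced_regions")
    if (!is.null(out_dir) && nrow(regions)) {
      write_bed(data.frame(chromosome = regions$chromosome,
                           start_bp = regions$start_bp,
                           end_bp = regions$end_bp,
                           label = paste0("region", regions$region_id)),
                file.path(out_dir, "reduced_regions.bed"))
    }
    summary$n_flagged_blocks <- length(flagged)
    summary$n_regions <- nrow(regions)
    summary$p_g1_vs_g2 <- comp12$mannwhitney_p
  }

  ## stage: ld
  if (!("ld" %in% skip)) {
    profiles <- lapply(groups, function(ids) {
      ld_profile(panel, ids, bin_kb = cfg$ld$bin_kb, max_kb = cfg$ld$max_kb)
    })
    res$ld_profiles <- profiles
    for (g in names(profiles)) {
      emit(as.data.frame(profiles[[g]]), paste0("ld_profile_", g))
    }
    summary$mean_delta_sq_group1 <-
      mean(attr(profiles$group1, "pairs")$delta_sq, na.rm = TRUE)
    summary$mean_delta_sq_group2 <-
      mean(attr(profiles$group2, "pairs")$delta_sq, na.rm = TRUE)
  }

  ## stage: novel
  if (!("novel" %in% skip) && !is.null(blocks)) {
    novel_snps <- find_novel_snps(panel,
                                  reference_group = cfg$novel$reference_group)
    counts <- count_novel_block_haplotypes(
      panel, blocks, reference_group = cfg$novel$reference_group)
    res$novel_snps <- novel_snps
    res$novel_counts <- counts
    emit(novel_snps, "novel_snps")
    emit(counts, "novel_counts")
    summary$n_novel_snps <- nrow(novel_snps)
    fit <- try(fit_accrual(counts), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      res$accrual <- fit
      summary$accrual_slope <- fit$slope
      summary$accrual_r_squared <- fit$r_squared
    }
  }

  ## stage: ancestry
  if (!("ancestry" %in% skip)) {
    ped <- if (!is.null(cfg$pedigree)) read_pedigree(cfg$pedigree)
      else if (!is.null(res$sim)) res$sim$truth$pedigree
    q <- if (!is.null(cfg$qmatrix)) read_qmatrix(cfg$qmatrix)
      else if (!is.null(res$sim)) res$sim$truth$qmatrix
    if (!is.null(ped) && nrow(ped)) {
      g23 <- unlist(groups[c("group2", "group3")], use.names = FALSE)
      g23 <- intersect(g23, ped$child)
      if (length(g23)) {
        ff <- founder_frequencies(ped, g23)
        res$founder_freq <- ff
        emit(as.data.frame(ff), "founder_frequencies")
        summary$top11_founder_share <- top_founder_share(ff, 11)
      }
    }
    if (!is.null(q)) {
      res$admixed <- classify_admixed(q, cfg$admixture_threshold)
      res$component_stats <- group_component_stats(q, groups)
      emit(res$component_stats$table, "component_stats")
      summary$n_admixed <- sum(res$admixed)
    }
    dist <- simple_matching_distance(panel)
    res$distance <- dist
    if (!is.null(out_dir)) {
      write_phylip_dist(dist, file.path(out_dir, "distances.phylip"))
    }
  }

  res$summary <- summary
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = cfg$seed, window = cfg$window, qc = cfg$qc,
           scan = cfg$scan, ld = cfg$ld, novel = cfg$novel,
           admixture_threshold = cfg$admixture_threshold, skip = skip),
      file.path(out_dir, "run_parameters.json"), auto_unbox = TRUE)
  }
  class(res) <- "hap_run"
  res
}

#' @export
print.hap_run <- function(x, ...) {
  cat("haplotype-dynamics pipeline run\n")
  for (k in names(x$summary)) {
    v <- x$summary[[k]]
    cat(sprintf("  %-24s %s\n", k,
                if (is.numeric(v) && v == round(v)) format(v)
                else format(signif(v, 4))))
  }
  invisible(x)
}
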