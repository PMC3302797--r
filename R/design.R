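#' Design constants of the reference Japanese rice panel
#'
#' Bookkeeping of the study design the simulator's defaults emulate: a
#' 177-accession Japanese rice panel (plus 3 foreign accessions) assayed
#' on 4224 array SNPs, of which 3259 were informative, analysed in three
#' breeding-phase groups. Provided so that analyses and documentation can
#' reference the design numerically instead of hard-coding counts.
#'
#' @return a list:
#' \describe{
#'   \item{informative_snps_by_donor}{named vector: informative SNP counts
#'     by donor cultivar of the discovery comparison (2093 + 493 + 673 =
#'     3259)}
#'   \item{assay_plexes}{sizes of the array multiplexes (3 x 768 + 384 +
#'     2 x 768 = 4224)}
#'   \item{group_totals}{accessions per breeding-phase group (63, 51, 63)}
#'   \item{non_irrigated}{non-irrigated accessions per group (22, 1, 0)}
#'   \item{n_chromosomes}{12}
#'   \item{genome_mb}{approximate genome size, 380 Mb}
#'   \item{year_range}{registration years of improved cultivars,
#'     1931-2005}
#'   \item{development_years}{typical years to develop and release a
#'     cultivar, 10}
#' }
#' @export
study_design <- function() {
  list(
    informative_snps_by_donor = c(koshihikari = 2093L, eiko = 493L,
                                  rikuu132 = 673L),
    assay_plexes = c(768L, 768L, 768L, 384L, 768L, 768L),
    group_totals = c(group1 = 63L, group2 = 51L, group3 = 63L),
    non_irrigated = c(group1 = 22L, group2 = 1L, group3 = 0L),
    n_chromosomes = 12L,
    genome_mb = 380,
    year_range = c(1931L, 2005L),
    development_years = 10L
  )
}
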