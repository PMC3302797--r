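Package: hapdyn
Title: Haplotype-Block Diversity Dynamics in Crop Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of how artificial selection reshapes
    haplotype structure across the phases of a breeding program. Provides
    SNP quality control for homozygous biallelic call panels, sliding
    five-SNP haplotype-block enumeration and per-group diversity indexing,
    scanning and merging of regions with breeding-driven diversity
    collapse, adjacent-pair linkage-disequilibrium (delta-squared)
    profiles with distance binning, detection of novel SNP alleles and
    haplotype polymorphisms with a registration-year accrual regression,
    pedigree founder-frequency analysis, admixture-group statistics, and a
    configurable breeding-program genotype simulator with recorded truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
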